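level,epsilon_kjmol,sigma_A
O,5.6,4.7
I,5.0,4.7
II,4.5,4.7
III,4.0,4.7
IV,3.5,4.7
V,3.1,4.7
VI,2.7,4.7
VII,2.3,4.7
VIII,2.0,4.7
IX,2.0,6.2
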