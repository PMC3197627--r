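type,Qda,Qd,Qa,Q0,P5,P4,P3,P2,P1,Nda,Nd,Na,N0,C5,C4,C3,C2,C1
Qda,O,O,O,II,O,O,O,I,I,I,I,I,IV,V,VI,VII,IX,IX
Qd,O,I,O,II,O,O,O,I,I,I,III,I,IV,V,VI,VII,IX,IX
Qa,O,O,I,II,O,O,O,I,I,I,I,III,IV,V,VI,VII,IX,IX
Q0,II,II,II,IV,I,O,I,II,III,III,III,III,IV,V,VI,VII,IX,IX
P5,O,O,O,I,O,O,O,O,O,I,I,I,IV,V,VI,VI,VII,VIII
P4,O,O,O,O,O,I,I,II,II,III,III,III,IV,V,VI,VII,VIII,VIII
P3,O,O,O,I,O,I,I,II,II,II,II,II,IV,V,V,VI,VII,VIII
P2,I,I,I,II,O,II,II,II,II,II,II,II,III,IV,IV,V,VI,VII
P1,I,I,I,III,O,II,II,II,II,II,II,II,III,IV,IV,IV,V,VI
Nda,I,I,I,III,I,III,II,II,II,II,II,II,IV,IV,V,VI,VI,VI
Nd,I,III,I,III,I,III,II,II,II,II,III,II,IV,IV,V,VI,VI,VI
Na,I,I,III,III,I,III,II,II,II,II,II,III,IV,IV,V,VI,VI,VI
N0,IV,IV,IV,IV,IV,IV,IV,III,III,IV,IV,IV,IV,IV,IV,IV,V,VI
C5,V,V,V,V,V,V,V,IV,IV,IV,IV,IV,IV,IV,IV,IV,V,V
C4,VI,VI,VI,VI,VI,VI,V,IV,IV,V,V,V,IV,IV,IV,IV,IV,IV
C3,VII,VII,VII,VII,VI,VII,VI,V,IV,VI,VI,VI,IV,IV,IV,IV,IV,IV
C2,IX,IX,IX,IX,VII,VIII,VII,VI,V,VI,VI,VI,V,V,IV,IV,IV,IV
C1,IX,IX,IX,IX,VIII,VIII,VIII,VII,VI,VI,VI,VI,VI,V,IV,IV,IV,IV
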