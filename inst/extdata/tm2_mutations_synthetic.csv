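id,position,from,to
WYm3,206,I,W
WYm3,207,A,Y
WYm3,208,L,I
WYm3,209,W,A
WYm3,210,Y,L
WYm2,207,A,W
WYm2,208,L,Y
WYm2,209,W,A
WYm2,210,Y,L
WYm1,208,L,W
WYm1,209,W,Y
WYm1,210,Y,L
WYp1,209,W,I
WYp1,210,Y,W
WYp1,211,I,Y
WYp2,209,W,I
WYp2,210,Y,R
WYp2,211,I,W
WYp2,212,R,Y
WYp3,209,W,I
WYp3,210,Y,R
WYp3,211,I,K
WYp3,212,R,W
WYp3,213,K,Y
W192A,192,W,A
W209A,209,W,A
W192A_W209A,192,W,A
W192A_W209A,209,W,A
F189R,189,F,R
W192R,192,W,R
W209R,209,W,R
T215K,215,T,K
T215R,215,T,R
L216R,216,L,R
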