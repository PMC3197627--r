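residue,bead,type,charge,atoms
ALA,BB,N0,0,N;CA;C;O
ARG,BB,N0,0,N;CA;C;O
ARG,SC1,N0,0,CB;CG;CD
ARG,SC2,Qd,1,NE;CZ;NH1;NH2
ASN,BB,N0,0,N;CA;C;O
ASN,SC1,P5,0,CB;CG;OD1;ND2
ASP,BB,N0,0,N;CA;C;O
ASP,SC1,Qa,-1,CB;CG;OD1;OD2
CYS,BB,N0,0,N;CA;C;O
CYS,SC1,C5,0,CB;SG
GLN,BB,N0,0,N;CA;C;O
GLN,SC1,P4,0,CB;CG;CD;OE1;NE2
GLU,BB,N0,0,N;CA;C;O
GLU,SC1,Qa,-1,CB;CG;CD;OE1;OE2
GLY,BB,N0,0,N;CA;C;O
HIS,BB,N0,0,N;CA;C;O
HIS,SC1,C4,0,CB;CG
HIS,SC2,P1,0,ND1;CE1
HIS,SC3,P1,0,CD2;NE2
ILE,BB,N0,0,N;CA;C;O
ILE,SC1,C1,0,CB;CG1;CG2;CD1
LEU,BB,N0,0,N;CA;C;O
LEU,SC1,C1,0,CB;CG;CD1;CD2
LYS,BB,N0,0,N;CA;C;O
LYS,SC1,C3,0,CB;CG;CD
LYS,SC2,Qd,1,CE;NZ
MET,BB,N0,0,N;CA;C;O
MET,SC1,C5,0,CB;CG;SD;CE
PHE,BB,N0,0,N;CA;C;O
PHE,SC1,C4,0,CB;CG
PHE,SC2,C4,0,CD1;CE1
PHE,SC3,C4,0,CD2;CE2;CZ
PRO,BB,N0,0,N;CA;C;O
PRO,SC1,C3,0,CB;CG;CD
SER,BB,N0,0,N;CA;C;O
SER,SC1,P1,0,CB;OG
THR,BB,N0,0,N;CA;C;O
THR,SC1,P1,0,CB;OG1;CG2
TRP,BB,N0,0,N;CA;C;O
TRP,SC1,C4,0,CB;CG
TRP,SC2,P1,0,CD1;NE1;CE2
TRP,SC3,C4,0,CD2;CE3
TRP,SC4,C4,0,CZ2;CZ3;CH2
TYR,BB,N0,0,N;CA;C;O
TYR,SC1,C4,0,CB;CG
TYR,SC2,C4,0,CD1;CE1
TYR,SC3,P1,0,CD2;CE2;CZ;OH
VAL,BB,N0,0,N;CA;C;O
VAL,SC1,C2,0,CB;CG1;CG2
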