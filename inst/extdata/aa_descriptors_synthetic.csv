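code,kind,one_letter,AlogP,Estate,PSA,Polar,HBA,HBD,RB,MW,chirality
ALA,NAA,A,-0.5818,22.0,63.32,21.2852,2,2,1,89.09,L
ARG,NAA,R,-1.3384,37.6667,125.22,44.762,3,5,5,174.2,L
ASN,NAA,N,-1.7263,34.1667,106.41,29.4226,3,3,3,132.12,L
ASP,NAA,D,-1.127,36.1667,100.62,27.864,3,3,3,133.1,L
CYS,NAA,C,-0.6719,24.7222,63.32,29.4642,3,3,2,121.16,L
GLU,NAA,E,-0.7369,37.6667,100.62,32.481,3,3,4,147.13,L
GLN,NAA,Q,-1.3362,35.6667,106.41,34.0396,3,3,4,146.15,L
GLY,NAA,G,-0.9703,20.1667,63.32,16.6902,2,2,1,75.07,achiral
HIS,NAA,H,-0.6359,32.6667,92.0,37.9029,3,3,3,155.16,L
ILE,NAA,I,0.4444,26.8333,63.32,35.0662,2,2,3,131.18,L
LEU,NAA,L,0.4444,26.8333,63.32,35.0662,2,2,3,131.18,L
LYS,NAA,K,-0.4727,30.0,89.34,38.5166,3,3,5,146.19,L
MET,NAA,M,0.1514,26.8333,63.32,38.6102,3,2,4,149.22,L
PHE,NAA,F,0.641,33.1667,63.32,45.7572,2,2,3,165.19,L
PRO,NAA,P,-0.177,23.0,49.33,28.6605,2,2,1,115.13,L
SER,NAA,S,-1.6094,27.5,83.55,22.697,3,3,2,105.09,L
THR,NAA,T,-1.2209,29.3333,83.55,27.292,3,3,2,119.12,L
TRP,NAA,W,1.1223,39.0,79.11,57.6139,2,3,3,204.23,L
TYR,NAA,Y,0.3466,38.8333,83.55,47.422,3,3,3,181.19,L
VAL,NAA,V,0.0543,25.3333,63.32,30.4492,2,2,2,117.15,L
pAcF,UAA,,0.8436,43.5,80.39,55.7617,3,2,4,207.23,L
pAzF,UAA,,1.5828,44.8333,112.08,54.5632,3,2,4,206.2,L
pBpa,UAA,,1.872,53.1667,80.39,75.6317,3,2,5,269.3,L
OMeY,UAA,,0.6496,38.3333,72.55,52.3092,3,2,4,195.22,L
IY3,UAA,,0.9512,40.62,83.55,60.139,3,3,3,307.09,L
NAEK,UAA,,0.6051,55.6667,150.41,62.8259,5,3,9,259.27,L
BocK,UAA,,1.0933,47.9167,101.65,63.6989,4,3,6,246.31,L
PrK,UAA,,-0.072,48.6667,101.65,57.6459,4,3,7,228.25,L
Anap,UAA,,1.8662,53.3333,92.42,78.0534,4,3,5,272.3,L
CouA,UAA,,0.453,54.3333,113.76,63.464,5,3,3,249.22,L
HPG,UAA,,-0.1883,29.5,63.32,33.6782,2,2,3,127.14,L
AHA,UAA,,0.0987,35.0,112.08,34.2412,3,2,4,144.13,L
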