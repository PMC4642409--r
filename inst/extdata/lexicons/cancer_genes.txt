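BRCA1
BRCA2
TP53
KRAS
NRAS
HRAS
EGFR
ERBB2
HER2
MYC
MYCN
PTEN
RB1
APC
MLH1
MSH2
MSH6
PMS2
ATM
CHEK2
PALB2
CDH1
STK11
VHL
RET
MET
ALK
ROS1
BRAF
PIK3CA
AKT1
CDKN2A
CDKN1B
SMAD4
NF1
NF2
WT1
KIT
PDGFRA
FLT3
NPM1
IDH1
IDH2
JAK2
ABL1
BCR
FGFR1
FGFR2
FGFR3
CCND1
CDK4
CDK6
MDM2
ESR1
PGR
AR
NTRK1
NTRK2
NTRK3
ERG
ETV6
RUNX1
GATA3
MAP2K1
MAP2K2
MTOR
TSC1
TSC2
SMO
PTCH1
GLI1
NOTCH1
CTNNB1
AXIN1
ARID1A
BAP1
SETD2
KDM6A
KMT2D
CREBBP
EP300
STAT3
SRC
YES1
FYN
RAF1
PIK3R1
FOXA1
SPOP
EZH2
SUZ12
DNMT3A
TET2
ASXL1
SF3B1
U2AF1
XPO1
MYB
MYBL2
BCL2
BCL6
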