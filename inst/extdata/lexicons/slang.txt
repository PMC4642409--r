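LOL
OMG
XOXO
XO
BRB
BTW
IMHO
IMO
LMAO
ROFL
TTYL
THX
TY
YW
IDK
FYI
ASAP
GR8
L8R
B4
CU
CYA
PLZ
NP
JK
FWIW
AFAIK
IRL
TGIF
OMW
SMH
TBH
NVM
HMU
ILY
WTG
BFF
GTG
TC
LY
HAGD
WBU
HBU
IKR
FTW
TMI
YOLO
BC
AML
CMF
RX
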