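label,midline,mirror_of,caudal_partner
FP1,FALSE,FP2,O1
FPZ,TRUE,,OZ
FP2,FALSE,,O2
AF3,FALSE,AF4,PO3
AF4,FALSE,,PO4
F7,FALSE,F8,P7
F5,FALSE,F6,P5
F3,FALSE,F4,P3
F1,FALSE,F2,P1
FZ,TRUE,,PZ
F2,FALSE,,P2
F4,FALSE,,P4
F6,FALSE,,P6
F8,FALSE,,P8
FT7,FALSE,FT8,TP7
FC5,FALSE,FC6,CP5
FC3,FALSE,FC4,CP3
FC1,FALSE,FC2,CP1
FCZ,TRUE,,CPZ
FC2,FALSE,,CP2
FC4,FALSE,,CP4
FC6,FALSE,,CP6
FT8,FALSE,,TP8
T7,FALSE,T8,
C5,FALSE,C6,
C3,FALSE,C4,
C1,FALSE,C2,
CZ,TRUE,,
C2,FALSE,,
C4,FALSE,,
C6,FALSE,,
T8,FALSE,,
TP7,FALSE,TP8,
CP5,FALSE,CP6,
CP3,FALSE,CP4,
CP1,FALSE,CP2,
CPZ,TRUE,,
CP2,FALSE,,
CP4,FALSE,,
CP6,FALSE,,
TP8,FALSE,,
P7,FALSE,P8,
P5,FALSE,P6,
P3,FALSE,P4,
P1,FALSE,P2,
PZ,TRUE,,
P2,FALSE,,
P4,FALSE,,
P6,FALSE,,
P8,FALSE,,
PO7,FALSE,PO8,
PO5,FALSE,PO6,
PO3,FALSE,PO4,
POZ,TRUE,,
PO4,FALSE,,
PO6,FALSE,,
PO8,FALSE,,
CB1,FALSE,CB2,
O1,FALSE,O2,
OZ,TRUE,,
O2,FALSE,,
CB2,FALSE,,
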