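# Drug-associated targets also associated with blood pressure and hypertension
# traits (published list; the published spelling "TNSFSF12" is stored under the
# registry symbol TNFSF12).
ADRB1
ENPEP
EPHA3
FGFR1
HBEGF
HCN4
IL6R
KCNH2
KCNJ5
MAPT
MC4R
MET
MYH6
MYL4
NDUFAF3
NDUFB10
NPR3
PDE3A
PDE4B
PRKCA
PSMB7
PTK2
SCN5A
SRD5A3
THRB
TNFSF12
TNFSF13
TNNT3
TUBB3
WT1
XPO1
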