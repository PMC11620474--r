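gene,pathway
IRA1,Ras/PKA
IRA2,Ras/PKA
CYR1,Ras/PKA
GPB1,Ras/PKA
GPB2,Ras/PKA
PDE2,Ras/PKA
RAS2,Ras/PKA
TOR1,TOR/Sch9
SCH9,TOR/Sch9
KSP1,TOR/Sch9
KOG1,TOR/Sch9
MKS1,RTG
RTG1,RTG
RTG2,RTG
RTG3,RTG
CIT1,TCA
KGD1,TCA
MDH1,TCA
MAE1,TCA
ALD5,TCA
PUF3,mitochondrial-biogenesis
PAB1,mitochondrial-biogenesis
PAN1,mitochondrial-biogenesis
PAN2,mitochondrial-biogenesis
PAN3,mitochondrial-biogenesis
AIM17,mitochondrial-biogenesis
MKT1,mitochondrial-biogenesis
HOG1,HOG
PBS2,HOG
SSK2,HOG
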