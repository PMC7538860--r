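ligand,receptor,db
FBN1,ITGAV,IUPHAR
SLIT2,ROBO1,DLRP
APP,LRP1,DLRP
APP,CD74,DLRP
CTGF,ERBB4,DLRP
COL3A1,DDR2,IUPHAR
COL1A1,DDR2,IUPHAR
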