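gene	n_positive_clones	in_map
ACVR1B	2	FALSE
ACVRL1	2	FALSE
ADRBK1	2	FALSE
ADRBK2	2	FALSE
AKT2	2	FALSE
ALS2CR7	2	FALSE
CAMK4	2	TRUE
CHEK1	2	FALSE
CHKB	2	FALSE
CIB4	2	FALSE
CKC42BP	2	FALSE
CKMT2	2	FALSE
CLK3	2	FALSE
CSNK1E	2	FALSE
DAPK2	2	TRUE
DCAMKL1	2	FALSE
DGKB	2	FALSE
DMPK	2	FALSE
DNAJC6	2	FALSE
EPHA2	2	FALSE
FASTKD3	2	FALSE
FLT4	2	FALSE
GRK1	2	FALSE
GSK3A	2	FALSE
KFZp686K16132	2	FALSE
KHK	2	FALSE
KSR1	2	FALSE
LOC392265	2	FALSE
MAP2K7	2	TRUE
MAPK11	2	FALSE
MAPK12	2	FALSE
MAPK13	2	FALSE
MAPK4	2	FALSE
MAPK6	2	FALSE
MGC16169	2	FALSE
MGC42105	2	FALSE
MINK1	2	FALSE
MPP7	2	FALSE
MYO3B	2	FALSE
NEK10	2	FALSE
NME5	2	FALSE
NME6	2	FALSE
NUAK2	2	FALSE
PDGFRL	2	FALSE
PFKL	2	FALSE
PHKB	2	FALSE
PHKG2	2	FALSE
PIK3R2	2	FALSE
PKMYT1	2	FALSE
PLK1	2	FALSE
PRKAB2	2	FALSE
PRKAG3	2	FALSE
PRKAR1A	2	FALSE
PRKAR1B	2	FALSE
PTK7	2	FALSE
RIOK2	2	FALSE
ROS1	2	FALSE
RPS6KA4	2	FALSE
SRPK3	2	FALSE
STK38	2	FALSE
TSSK6	2	FALSE
TTN	2	FALSE
ULK1	2	FALSE
YES1	2	FALSE
CALM1	3	TRUE
CAMK1D	3	TRUE
DAPK1	3	TRUE
DAPK3	3	TRUE
DGKG	3	FALSE
EPHA3	3	FALSE
EPHB2	3	FALSE
ERBB4	3	TRUE
GUCY2D	3	FALSE
LOC441655	3	FALSE
MAP2K2	3	TRUE
MAPK9	3	TRUE
MPP3	3	FALSE
MYLK3	3	TRUE
PAG1	3	TRUE
RAGE	3	FALSE
ROCK1	3	TRUE
RPS6KB2	3	FALSE
TESK1	3	FALSE
TLK2	3	FALSE
TNIK	3	FALSE
CSK	4	TRUE
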