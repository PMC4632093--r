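DAPK3	physical	DAPK1
DAPK3	physical	DAPK2
DAPK3	functional	ROCK1
DAPK3	functional	MYL2
DAPK3	functional	MYL9
DAPK3	functional	DAXX
DAPK3	functional	NR3C1
DAPK3	functional	ATF4
DAPK3	functional	PAWR
DAPK3	functional	PRKCZ
DAPK3	functional	GRB14
DAPK3	functional	F2RL3
DAPK3	functional	PPP1R12A
BIK	functional	TP53
TP53	functional	DAPK1
TP53	functional	MAPK9
DAPK1	functional	CAMK1D
DAPK2	functional	CAMK1D
DAPK1	functional	CAMK4
DAPK2	functional	CAMK4
MYL2	functional	MYLK3
MYL9	functional	MYLK3
ROCK1	functional	MYL2
ROCK1	functional	MYL9
CAMK1D	functional	CALM1
CAMK4	functional	CALM1
DAPK1	functional	CALM1
DAPK2	functional	CALM1
MAP2K2	functional	MAP2K7
MAPK9	functional	MAP2K7
ERBB4	functional	STAT3
ROCK1	functional	STAT3
STAT3	physical	PAG1
ERBB4	functional	PAG1
ERBB4	functional	STAT5A
PAG1	physical	CSK
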