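label	network	x	y	z	radius
dACC_L	CON	-6	18	30	5
dACC_R	CON	6	18	30	5
preSMA	CON	0	8	52	5
SMA	CON	0	-4	58	5
FrOper_L	CON	-42	16	6	5
FrOper_R	CON	42	16	6	5
aIns_L	CON	-36	18	-2	5
aIns_R	CON	36	18	-2	5
PCC	DMN	-2	-52	26	5
Precuneus	DMN	0	-62	38	5
mFP	DMN	-2	56	12	5
mFG	DMN	0	46	20	5
AG_L	DMN	-46	-62	32	5
AG_R	DMN	50	-58	28	5
MTL_L	DMN	-26	-20	-14	5
MTL_R	DMN	26	-20	-14	5
OFC_L	OST	-26	28	-16	5
OFC_R	OST	26	28	-16	5
dCaud_L	OST	-13	15	9	5
dCaud_R	OST	13	15	9	5
dcPut_L	OST	-28	1	3	5
dcPut_R	OST	28	1	3	5
Thal_L	OST	-10	-18	8	5
Thal_R	OST	10	-18	8	5
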