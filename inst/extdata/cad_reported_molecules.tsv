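molecule	synonyms	layer	tag	down13	up13	nr13	down15	up15	nr15	down20	up20	nr20	reported
hsa-mir-144	hsa-mir-144	MIR	MIR	50	0	50	0	0	100	0	0	100	2
hsa-miR-505-3p	hsa-miR-505-3p	MIR	MIR	50	0	50	0	0	100	0	0	100	2
hsa-let-7c	hsa-let-7c	MIR	MIR	0	50	50	0	50	50	0	50	50	2
hsa-mir-1303	hsa-mir-1303	MIR	MIR	0	50	50	0	50	50	0	50	50	2
hsa-mir-1305	hsa-mir-1305	MIR	MIR	0	50	50	0	50	50	0	50	50	2
hsa-mir-943	hsa-mir-943	MIR	MIR	0	50	50	0	50	50	0	50	50	2
hsa-miR-579-3p	hsa-miR-579-3p	MIR	MIR	0	50	50	0	50	50	0	50	50	2
hsa-miR-10a-5p	hsa-miR-10a-5p	MIR	MIR	50	50	0	50	0	50	50	0	50	2
hsa-mir-362	hsa-mir-362	MIR	MIR	50	0	50	50	0	50	50	0	50	2
hsa-mir-20a	hsa-mir-20a	MIR	MIR	50	0	50	50	0	50	50	0	50	2
hsa-mir-576	hsa-mir-576	MIR	MIR	50	50	0	50	0	50	50	0	50	2
hsa-miR-106b-5p	hsa-miR-106b-5p	MIR	MIR	100	0	0	50	0	50	50	0	50	2
hsa-miR-517a-3p	hsa-miR-517a-3p	MIR	MIR	100	0	0	50	0	50	50	0	50	2
hsa-mir-636	hsa-mir-636	MIR	MIR	50	0	50	50	0	50	50	0	50	2
hsa-mir-661	hsa-mir-661	MIR	MIR	50	0	50	50	0	50	50	0	50	2
hsa-mir-132	hsa-mir-132	MIR	MIR	50	50	0	50	0	50	50	0	50	2
hsa-miR-21-5p	hsa-miR-21-5p	MIR	MIR	50	0	50	50	0	50	50	0	50	2
hsa-miR-1255b-5p	hsa-miR-1255b-5p	MIR	MIR	50	0	50	50	0	50	50	0	50	2
APOB	APOB	PRO	TP	28.6	0	71	14.3	0	86	0	0	100	7
APOA4	APOA4|ApoA-IV|APOA-IV	PRO	TP	66.7	0	33	16.7	0	83	16.7	0	83	6
TMSB4X	TMSB4X|TB4X|THYB4	PRO	CS	0	80	20	0	80	20	0	60	40	5
APCS	APCS|PTX2	PRO	DIS	80	0	20	60	0	40	40	0	60	5
ADIPOQ	ADIPOQ|ACDC|ACRP30	PRO	CS	60	0	40	0	0	100	0	0	100	5
APOA1	APOA1	PRO	TP	80	0	20	60	0	40	0	0	100	5
PRDX2	PRDX2|NKEFB|TDPX1	PRO	ENZ	0	0	100	0	0	100	0	0	100	4
APOC2	APOC2|APC2	PRO	TP	33.3	33	33	33.3	33	33	0	0	100	3
VTN	VTN	PRO	CS	0	67	33	0	0	100	0	0	100	3
GPX3	GPX3|GPXP	PRO	ENZ	33.3	0	67	33.3	0	67	33.3	0	67	3
APOC1	APOC1|APOC1B	PRO	TP	33.3	0	67	33.3	0	67	33.3	0	67	3
ACTG1	ACTG1|ACTG	PRO	CS	0	100	0	0	100	0	0	50	50	2
ALB	ALB|GIG20|GIG42	PRO	TP	0	0	100	0	0	100	0	0	100	2
AMBP	AMBP|ITIL|HCP	PRO	INH	0	100	0	0	50	50	0	0	100	2
APOL1	APOL1|APOL	PRO	TP	50	0	50	50	0	50	0	0	100	2
MPO	MPO	PRO	ENZ	50	50	0	50	0	50	50	0	50	2
LysoPC(18:2(9Z,12Z))	LysoPC(18:2(9Z,12Z))	MET	MET	75	25	0	0	25	75	0	25	75	4
LysoPC(22:6(4Z,7Z,10Z,13Z,16Z,19Z))	LysoPC(22:6(4Z,7Z,10Z,13Z,16Z,19Z))	MET	MET	50	25	25	25	25	50	0	25	75	4
LysoPC(18:1(9Z))	LysoPC(18:1(9Z))	MET	MET	75	25	0	25	25	50	0	25	75	4
LysoPE(0:0/18:2(9Z,12Z))	LysoPE(0:0/18:2(9Z,12Z))	MET	MET	75	25	0	0	25	75	0	25	75	4
LysoPC(18:3(9Z,12Z,15Z))	LysoPC(18:3(9Z,12Z,15Z))	MET	MET	75	0	25	25	0	75	0	0	100	4
LysoPC(14:0/0:0)	LysoPC(14:0/0:0)	MET	MET	75	0	25	25	0	75	25	0	75	4
LysoPC(18:0)	LysoPC(18:0)	MET	MET	75	0	25	50	0	50	25	0	75	4
LysoPC(16:1(9Z)/0:0)	LysoPC(16:1(9Z)/0:0)	MET	MET	100	0	0	50	0	50	25	0	75	4
LysoPE(16:0/0:0)	LysoPE(16:0/0:0)	MET	MET	50	0	50	0	0	100	0	0	100	4
LysoPC(20:4(5Z,8Z,11Z,14Z))	LysoPC(20:4(5Z,8Z,11Z,14Z))	MET	MET	25	0	75	0	0	100	0	0	100	4
LysoPC(18:4(6Z,9Z,12Z,15Z))	LysoPC(18:4(6Z,9Z,12Z,15Z))	MET	MET	75	25	0	0	25	75	0	25	75	4
LysoPC(15:0)	LysoPC(15:0)	MET	MET	66.7	33	0	33.3	33	33	0	33	67	3
Phytosphingosine	Phytosphingosine	MET	MET	66.7	33	0	66.7	0	33	33.3	0	67	3
Palmitic acid	Palmitic acid	MET	MET	66.7	33	0	33.3	0	67	33.3	0	67	3
LysoPE(0:0/18:0)	LysoPE(0:0/18:0)	MET	MET	33.3	0	67	0	0	100	0	0	100	3
LysoPE(20:4(5Z,8Z,11Z,14Z)/0:0)	LysoPE(20:4(5Z,8Z,11Z,14Z)/0:0)	MET	MET	0	33	67	0	0	100	0	0	100	3
L-tyrosine	L-tyrosine	MET	MET	50	50	0	0	0	100	0	0	100	2
Dehydroepiandrosterone sulfate (DHEA)	Dehydroepiandrosterone sulfate (DHEA)	MET	MET	50	50	0	0	50	50	0	0	100	2
L-arginine	L-arginine	MET	MET	50	50	0	0	50	50	0	50	50	2
LysoPE(18:2(9Z,12Z)/0:0)	LysoPE(18:2(9Z,12Z)/0:0)	MET	MET	50	50	0	0	50	50	0	50	50	2
Alpha-linolenic acid (ALA)	Alpha-linolenic acid (ALA)	MET	MET	50	50	0	50	0	50	50	0	50	2
N-Palmitoylethanolamide (PEA)	N-Palmitoylethanolamide (PEA)	MET	MET	100	0	0	100	0	0	0	0	100	2
Cer(d18:0/16:0)	Cer(d18:0/16:0)	MET	MET	0	100	0	0	50	50	0	50	50	2
Pregnenolone sulfate	Pregnenolone sulfate	MET	MET	100	0	0	100	0	0	50	0	50	2
PC(16:0/0:0)[rac]	PC(16:0/0:0)[rac]	MET	MET	0	0	100	0	0	100	0	0	100	2
PE(21:0/0:0)	PE(21:0/0:0)	MET	MET	0	0	100	0	0	100	0	0	100	2
LysoPC(22:5(7Z,10Z,13Z,16Z,19Z))	LysoPC(22:5(7Z,10Z,13Z,16Z,19Z))	MET	MET	50	0	50	0	0	100	0	0	100	2
L-valine	L-valine	MET	MET	0	50	50	0	0	100	0	0	100	2
LysoPE(18:1(9Z)/0:0)	LysoPE(18:1(9Z)/0:0)	MET	MET	100	0	0	0	0	100	0	0	100	2
LysoPE(18:0/0:0)	LysoPE(18:0/0:0)	MET	MET	0	0	100	0	0	100	0	0	100	2
LysoPE(0:0/20:1(11Z))	LysoPE(0:0/20:1(11Z))	MET	MET	50	0	50	0	0	100	0	0	100	2
2-Hydroxybutyric acid	2-Hydroxybutyric acid	MET	MET	0	50	50	0	0	100	0	0	100	2
L-Acetylcarnitine (ALCAR or ALC)	L-Acetylcarnitine (ALCAR or ALC)	MET	MET	0	50	50	0	0	100	0	0	100	2
Glycine	Glycine	MET	MET	50	0	50	0	0	100	0	0	100	2
LysoPE(0:0/22:5(4Z,7Z,10Z,13Z,16Z))	LysoPE(0:0/22:5(4Z,7Z,10Z,13Z,16Z))	MET	MET	50	0	50	0	0	100	0	0	100	2
L-histidine	L-histidine	MET	MET	50	0	50	0	0	100	0	0	100	2
LysoPC(22:5(4Z,7Z,10Z,13Z,16Z))	LysoPC(22:5(4Z,7Z,10Z,13Z,16Z))	MET	MET	50	50	0	0	0	100	0	0	100	2
Cortisol	Cortisol	MET	MET	0	50	50	0	50	50	0	50	50	2
Docosahexaenoic acid (DHA)	Docosahexaenoic acid (DHA)	MET	MET	50	0	50	50	0	50	50	0	50	2
8,11,14-Eicosatrienoic acid (DGLA)	8,11,14-Eicosatrienoic acid (DGLA)	MET	MET	50	0	50	50	0	50	50	0	50	2
Icosanoic acid (eicosanoic acid)	Icosanoic acid (eicosanoic acid)	MET	MET	50	50	0	50	0	50	50	0	50	2
1,7-dimethylxanthine (paraxanthine)	1,7-dimethylxanthine (paraxanthine)	MET	MET	50	50	0	50	0	50	50	0	50	2
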