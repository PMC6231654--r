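study_id	layer	compartment	n_total	case_label	control_label	detection_method
Exp25790721	MET	plasma	18	CAD	healthy	LC-MS/MS
Exp26932197a	MET	plasma	102	CHD	healthy	HPLC-MS
Exp27394176a	MET	serum	109	CAD	healthy	UPLC-QTOF/MS
Exp27470195a	MET	plasma	43	T2DM-CHD	healthy	1D-1H-NMR
Exp27634119a	MET	plasma	392	NOCA	normal coronary artery	LC-QTOF-MS
Exp27634119k	MET	plasma	1086	significant CAD	non-significant CAD	LC-QTOF-MS
Exp28414761c	MET	plasma	15	stable CAD, time of catheterization, T0	stable CAD, time of catheterization, >3 months	UPLC-MS/MS and GC-MS
Exp28414761f	MET	plasma	15	stable CAD, time of catheterization, T6	stable CAD, time of catheterization, >3 months	UPLC-MS/MS and GC-MS
Exp28924163	MET	plasma	120	early-stage CAS	angiographically normal	LC-QTOF/MS
Exp29127404	MET	plasma	300	severe obstructive CHD	angiographically normal	UHPLC-QTOF/MS
Exp22022480	MIR	platelets	24	premature CAD	healthy	miRNA-array [IlluHSAv2MirRNA]
Exp28205634	MIR	plasma	6	CAD	healthy	miRNA-array [TaqMan OpenHSA]
Exp23216991	PRO	serum	354	CAD	insignificant CAD	Searchlight ProtArray
Exp24859250	PRO	plasma	20	CHD	healthy	nanoLC-MS/MS
Exp27350024a1	PRO	plasma	4	CAD discovery phase	healthy	MALDI-TOF/TOF
Exp27350024a2	PRO	plasma	4	CAD discovery phase	healthy	MALDI-TOF/TOF
Exp27350024a3	PRO	plasma	4	CAD discovery phase	healthy	MALDI-TOF/TOF
Exp27350024a4	PRO	plasma	4	CAD discovery phase	healthy	MALDI-TOF/TOF
Exp27350024a5	PRO	plasma	4	CAD discovery phase	healthy	MALDI-TOF/TOF
Exp27350024b	PRO	plasma	40	CAD verification phase	healthy	ELISA
Exp27350024c	PRO	plasma	506	CAD validation phase	healthy	ELISA
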