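name	x	y	z	radius	label_id
ACC	-2	42	12	6	NA
Cun	-4	-64	24	6	NA
L_IFG	-38	22	-12	6	NA
L_Ins	-38	16	-8	6	NA
L_SFG	-10	44	32	6	NA
L_TP	-40	24	-20	6	NA
SFG_BA9	-12	45	34	6	NA
SFG_BA10	-2	56	8	6	NA
PCC_Prec	-2	-60	20	6	NA
L_Amy	NA	NA	NA	NA	1
R_Amy	NA	NA	NA	NA	2
L_Hip	NA	NA	NA	NA	3
R_Hip	NA	NA	NA	NA	4
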