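chromosome	probe_id	nearest_gene	delta_percent	p_value	fdr_published
5	cg16361890	MAML1	-7.8	8.19e-08	0.001
22	cg00615377	RBFOX2	-5.3	1.20e-07	0.001
9	cg12971694	CD72	-9.0	2.05e-06	0.013
12	cg22566906	GRASP	-7.8	7.27e-06	0.029
4	cg02635407	SH3TC1	-9.6	7.47e-06	0.029
11	cg25634666	FOLR3	-10.8	3.23e-05	0.080
10	cg18390025	ELOVL3	-8.4	3.40e-05	0.080
5	cg10257049	FAXDC2	-7.5	3.58e-05	0.080
19	cg27461196	FXYD1/LGI4	-11.9	4.27e-05	0.080
6	cg00333528	GABRR1	-8.0	4.43e-05	0.080
21	cg17356733	IFNGR2	-11.9	4.56e-05	0.080
17	cg24489015	LPO	-10.8	5.82e-05	0.094
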