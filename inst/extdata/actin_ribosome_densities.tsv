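name	gene_symbol	protein_acc	mrna_acc	composite_density
beta-cytoplasmic actin	Actb	NP_031419	NM_007393	1351.607
alpha-smooth muscle actin	Acta2	NP_031418	NM_007392	53.781
alpha-skeletal actin	Acta1	NP_033736	NM_009606	10.267
alpha-cardiac actin	Actc1	NP_033738	NM_009608	3.872
gamma-cytoplasmic actin	Actg1	NP_033739	NM_009609	1.289
gamma-enteric smooth muscle actin	Actg2	NP_033740	NM_009610	0.377
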