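# demo scoring file: 5 eGFR-lowering-allele weights (synthetic)
variant_id	chr	pos	effect_allele	other_allele	effect_weight	effect_allele_freq	imputation_r2
rs1001	1	752566	A	G	0.0021	0.35	0.98
rs1002	2	1834721	T	C	0.0044	0.12	0.95
rs1003	7	922004	C	G	0.0016	0.61	0.92
rs1004	11	5510427	G	A	-0.0019	0.735	0.77
rs1005	19	45411941	C	T	0.0062	0.87	0.99
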