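chr	start	end	class	TargetGene	CellType	ABC.Score
chr1	100	400	promoter	GENE_A	microglia	0.21
chr1	1000	1500	enhancer	GENE_A	microglia	0.05
chr1	2200	2500	enhancer	GENE_B	microglia	0.03
chr1	2900	3100	enhancer	GENE_B	microglia	0.015
chr1	3400	3900	enhancer	GENE_B	microglia	0.08
chr1	100	400	promoter	GENE_B	astrocyte	0.12
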