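variant_id	spliceAI_AG	spliceAI_AL	spliceAI_DG	spliceAI_DL	phyloP	GERP	CADD	popMAF
chr1:120:A:T	0.129	0.043	0.252	0.034	0.95	0.74	1.8	0.00363
chr1:180:G:C	0.303	0.022	0.54	0.344	3.64	1.42	3.4	0.0233
chr1:1050:T:G	0.042	0.332	0.737	0.21	-1.87	2.41	14.5	0.017
chr1:2300:G:A	0.284	0.232	0.088	0.263	1.07	3.18	29.4	0.0345
chr1:2950:C:T	0.387	0.188	0.867	0.092	0.59	-0.05	24.3	0.0257
chr1:4100:A:G	0.081	0.146	0.152	0.288	-1.47	3.53	16.3	0.0258
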