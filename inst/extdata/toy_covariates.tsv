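sample_id	phenotype	age	sex	pc1	ancestry
S01	0	69.7	0	-1.845	AFR
S02	0	71.7	0	-0.139	AFR
S03	0	78.3	0	-0.447	AFR
S04	0	65.5	0	1.48	EUR
S05	0	85	0	-0.999	EUR
S06	0	67.8	0	-0.504	AFR
S07	0	78.5	0	2.04	AFR
S08	1	79.3	0	-1.322	AFR
S09	1	80.5	1	1.48	EUR
S10	0	82.9	0	0.394	EUR
S11	1	68.1	0	2.357	EUR
S12	1	72.8	0	-0.269	AFR
S13	0	88.6	0	-0.583	EUR
S14	0	77.5	0	1.515	EUR
S15	1	68.4	0	1.003	EUR
S16	0	86.7	1	0.677	EUR
S17	0	70.1	1	-2.823	AFR
S18	1	88.1	0	-0.255	EUR
S19	0	87.2	0	-0.049	AFR
S20	0	68.4	0	-0.476	AFR
S21	0	84.6	0	-0.547	AFR
S22	0	76.3	1	-1.335	EUR
S23	1	68.4	1	-0.359	AFR
S24	0	87.1	0	-1.738	EUR
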