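taxon	region	size	pct_a	pct_t	pct_g	pct_c	at_pct	gc_pct	at_skew	gc_skew
Pteronura_brasiliensis	mtDNA	16395	32.5	28.0	14.3	25.2	60.5	39.5	0.074	-0.276
Pteronura_brasiliensis	PCGs	11414	30.6	29.7	14.0	25.6	60.3	39.7	0.015	-0.293
Pteronura_brasiliensis	tRNAs	1515	33.1	31.2	18.5	17.2	64.3	35.7	0.030	0.036
Pteronura_brasiliensis	rRNAs	2532	36.1	24.0	18.2	21.7	60.1	39.9	0.201	-0.088
Pteronura_brasiliensis	D-loop	1010	29.7	27.9	15.5	26.8	57.6	42.4	0.031	-0.267
Lontra_canadensis	mtDNA	16500	31.3	25.9	15.5	27.2	57.2	42.7	0.094	-0.274
Lontra_canadensis	PCGs	11412	29.0	27.4	15.5	28.1	56.4	43.6	0.028	-0.289
Lontra_canadensis	tRNAs	1512	31.9	30.6	19.7	17.8	62.5	37.5	0.021	0.051
Lontra_canadensis	rRNAs	2530	36.0	22.8	18.5	22.6	58.8	41.1	0.224	-0.100
Lontra_canadensis	D-loop	1123	30.0	26.0	16.4	27.6	56.0	44.0	0.071	-0.255
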