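taxon	pct_t	pct_a	at_pct	at_skew	pct_c	pct_g	gc_pct	gc_skew
Pteronura_brasiliensis	28.0	32.5	60.5	0.074	25.2	14.3	39.5	-0.276
Lontra_canadensis	25.9	31.3	57.2	0.094	27.2	15.5	42.8	-0.274
Hydrictis_maculicollis	26.9	31.8	58.7	0.083	26.4	14.8	41.3	-0.281
Aonyx_cinerea	25.3	31.7	57.0	0.112	28.0	15.0	43.0	-0.303
Aonyx_capensis	25.6	31.7	57.3	0.107	27.9	14.8	42.7	-0.307
Enhydra_lutris	26.4	32.5	58.9	0.104	26.9	14.2	41.1	-0.308
Lutra_lutra	25.8	32.3	58.1	0.112	27.5	14.4	41.9	-0.313
Lutrogale_perspicillata	25.5	31.1	56.6	0.100	28.0	15.4	43.4	-0.289
Lutra_sumatrana	25.8	32.6	58.3	0.116	27.5	14.2	41.7	-0.318
Mustela_frenata	27.4	33.3	60.8	0.096	25.8	13.5	39.2	-0.314
Mustela_eversmannii	27.3	32.8	60.0	0.091	26.1	13.9	40.0	-0.305
Mustela_itatsi	27.5	33.0	60.5	0.091	25.7	13.7	39.5	-0.304
Mustela_nigripes	27.2	32.9	60.1	0.095	26.2	13.8	39.9	-0.310
Mustela_putorius	27.4	32.8	60.2	0.091	26.0	13.8	39.8	-0.308
Mustela_erminea	26.6	33.4	60.1	0.113	26.5	13.4	39.9	-0.327
Mustela_kathiah	27.9	33.3	61.1	0.088	25.3	13.6	38.9	-0.301
Mustela_nivalis	27.3	32.6	60.0	0.088	26.0	14.0	40.0	-0.299
Mustela_sibirica	27.3	32.9	60.2	0.093	26.0	13.9	39.8	-0.304
Mustela_altaica	27.6	32.8	60.3	0.087	25.8	13.9	39.7	-0.301
Vormela_peregusna	27.6	33.4	61.0	0.095	26.1	12.9	39.0	-0.338
Galictis_vittata	26.8	32.3	59.2	0.093	26.3	14.5	40.8	-0.290
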