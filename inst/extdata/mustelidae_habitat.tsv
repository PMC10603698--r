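taxon	code
Pteronura_brasiliensis	1
Lontra_canadensis	1
Hydrictis_maculicollis	1
Aonyx_cinerea	1
Aonyx_capensis	1
Enhydra_lutris	1
Lutra_lutra	1
Lutrogale_perspicillata	1
Lutra_sumatrana	1
Mustela_frenata	0
Mustela_eversmannii	0
Mustela_itatsi	0
Mustela_nigripes	0
Mustela_putorius	0
Mustela_erminea	0
Mustela_kathiah	0
Mustela_nivalis	0
Mustela_sibirica	0
Mustela_altaica	0
Vormela_peregusna	0
Galictis_vittata	0
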