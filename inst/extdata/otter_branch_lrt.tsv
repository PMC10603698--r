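gene	omega_background	omega_foreground	two_dlnl	p_printed
ND1	0.0147	0.0233	4.2566	0.0391
ND4	0.0226	0.0355	7.6079	<0.01
ND4L	0.0226	0.0355	7.6079	<0.01
ND5	0.0491	0.0628	4.0296	0.0447
COX3	0.0253	0.0493	15.3550	<0.01
CYTB	0.0253	0.0493	15.3550	<0.01
ND2	0.0632	0.0665	0.1480	0.7004
ND3	0.0332	0.0459	1.3190	0.2508
ND6	0.0182	0.0264	1.5611	0.2115
COX1	0.0121	0.0085	1.9831	0.1591
COX2	0.0145	0.0173	0.3077	0.5791
ATP6	0.0338	0.0506	3.4832	0.0620
ATP8	0.1867	0.2720	1.6266	0.2022
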