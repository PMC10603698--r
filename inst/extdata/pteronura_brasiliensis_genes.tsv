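gene	start	end	strand	category	start_codon	stop_codon
tRNA-Phe	1	69	+	tRNA
12S-rRNA	72	1033	+	rRNA
tRNA-Val	1034	1101	+	tRNA
16S-rRNA	1102	2670	+	rRNA
tRNA-Leu1	2671	2745	+	tRNA
ND1	2748	3704	+	PCG	ATG	TAG
tRNA-Ile	3704	3772	+	tRNA
tRNA-Gln	3770	3843	-	tRNA
tRNA-Met	3845	3913	+	tRNA
ND2	3914	4957	+	PCG	ATC	TAG
tRNA-Trp	4956	5023	+	tRNA
tRNA-Ala	5033	5101	-	tRNA
tRNA-Asn	5103	5175	-	tRNA
tRNA-Cys	5209	5275	-	tRNA
tRNA-Tyr	5276	5343	-	tRNA
COX1	5345	6889	+	PCG	ATG	TAA
tRNA-Ser1	6887	6955	-	tRNA
tRNA-Asp	6962	7028	+	tRNA
COX2	7029	7712	+	PCG	ATG	TAA
tRNA-Lys	7716	7783	+	tRNA
ATP8	7785	7988	+	PCG	ATG	TAA
ATP6	7946	8626	+	PCG	ATG	TAA
COX3	8626	9410	+	PCG	ATG	TA-
tRNA-Gly	9410	9479	+	tRNA
ND3	9480	9827	+	PCG	ATA	TAA
tRNA-Arg	9828	9895	+	tRNA
ND4L	9896	10192	+	PCG	GTG	TAA
ND4	10186	11563	+	PCG	ATG	T--
tRNA-His	11564	11632	+	tRNA
tRNA-Ser2	11633	11694	+	tRNA
tRNA-Leu2	11695	11764	+	tRNA
ND5	11765	13585	+	PCG	ATT	TAA
ND6	13570	14102	-	PCG	ATG	TA-
tRNA-Glu	14103	14171	-	tRNA
CYTB	14176	15315	+	PCG	ATG	AGA
tRNA-Thr	15316	15383	+	tRNA
tRNA-Pro	15384	15449	-	tRNA
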