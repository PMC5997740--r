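name	length_genes	mutation_mean	recomb_mean	is_sex_pair
chr1	2048	0.0512820512820513	2.86	FALSE
chr2	1280	0.032051282051282	2.69	FALSE
chr3	1152	0.0288461538461538	2.23	FALSE
chr4	768	0.0192307692307692	2.14	FALSE
chr5	896	0.0224358974358974	2.04	FALSE
chr6	1024	0.0256410256410256	1.92	FALSE
chr7	896	0.0224358974358974	1.87	FALSE
chr8	768	0.0192307692307692	1.68	FALSE
chr9	768	0.0192307692307692	1.66	FALSE
chr10	768	0.0192307692307692	1.81	FALSE
chr11	1280	0.032051282051282	1.58	FALSE
chr12	1024	0.0256410256410256	1.75	FALSE
chr13	384	0.00961538461538462	1.26	FALSE
chr14	640	0.016025641025641	1.2	FALSE
chr15	640	0.016025641025641	1.42	FALSE
chr16	896	0.0224358974358974	1.35	FALSE
chr17	1152	0.0288461538461538	1.29	FALSE
chr18	256	0.00641025641025641	1.17	FALSE
chr19	1408	0.0352564102564103	1.08	FALSE
chr20	512	0.0128205128205128	1.08	FALSE
chr21	256	0.00641025641025641	0.62	FALSE
chr22	384	0.00961538461538462	0.74	FALSE
chrX	768	0.0192307692307692	1.8	TRUE
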