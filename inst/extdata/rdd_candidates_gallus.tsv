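chrom	pos	dna_base	rdd_base	gene_id	gene_name	consequence	n_edited_replicates	mean_depth	sd_depth	mean_freq	sd_freq	tested
1	36367200	A	G	ENSGALG00000027799	TMEM19	3_prime_UTR_variant	2	25	2.83	0.27	0.11	FALSE
1	74991790	T	C	ENSGALG00000014342	TEAD4	downstream_gene_variant,intron_variant	7	27.14	9.44	0.38	0.1	FALSE
1	74992334	T	C	ENSGALG00000014342	TEAD4	downstream_gene_variant,intron_variant	3	38.33	12.34	0.46	0.07	FALSE
1	74992422	T	C	ENSGALG00000014342	TEAD4	downstream_gene_variant,intron_variant	3	30.33	6.66	0.3	0.06	FALSE
1	74993229	T	C	ENSGALG00000014342	TEAD4	downstream_gene_variant,intron_variant	3	25.33	7.51	0.39	0.06	FALSE
1	167109833	A	G	ENSGALG00000016980	COG3	missense_variant	4	100.25	32.8	0.47	0.08	TRUE
2	86000822	T	C	ENSGALG00000013191	NDUFS6	upstream_gene_variant	5	73.2	19.64	0.42	0.06	TRUE
2	86000881	T	C	ENSGALG00000013191	NDUFS6	upstream_gene_variant	2	114.5	36.06	0.21	0	FALSE
2	86000926	T	C	ENSGALG00000013191	NDUFS6	upstream_gene_variant	5	113.2	64.58	0.48	0.06	TRUE
2	86001360	T	C	ENSGALG00000013191	NDUFS6	upstream_gene_variant	4	61.75	24.92	0.26	0.06	TRUE
2	86001370	T	C	ENSGALG00000013191	NDUFS6	upstream_gene_variant	5	55.8	26.13	0.43	0.09	TRUE
2	110994632	A	G	-	-	intergenic_variant	3	29.33	3.79	0.67	0.11	FALSE
3	2384093	A	G	-	-	intergenic_variant	5	21.8	6.26	0.28	0.13	TRUE
3	2384105	A	G	-	-	intergenic_variant	2	23	9.9	0.34	0.06	TRUE
3	38271681	T	C	ENSGALG00000011013	PCNXL2	splice_region_variant,synonymous_variant	2	40	16.97	0.87	0.01	FALSE
4	17996546	T	C	-	-	intergenic_variant	3	24.33	7.09	0.27	0.04	FALSE
4	17999411	T	C	ENSGALG00000009128	novel gene	downstream_gene_variant	3	36	14.42	0.3	0.07	FALSE
4	17999509	T	C	ENSGALG00000009128	novel gene	downstream_gene_variant	5	33	14.82	0.26	0.05	FALSE
4	20956439	A	G	ENSGALG00000009405	GRIA2	missense_variant,splice_region_variant	5	48	53.30	0.42	0.09	TRUE
4	73361456	A	G	ENSGALG00000014395	DHX15	downstream_gene_variant	4	25.5	3.87	0.39	0.16	TRUE
6	15730446	A	G	ENSGALG00000005243	PPP3CB	intron_variant	2	18.5	4.95	0.38	0.25	FALSE
6	29787642	A	C	ENSGALG00000009427	TIAR	intron_variant	4	49.5	14.84	0.29	0.12	TRUE
6	34848568	A	G	ENSGALG00000010517	TCTN3	downstream_gene_variant	3	34	7	0.2	0.04	FALSE
12	2800528	T	C	ENSGALG00000003738 ENSGALG00000003799	EMC3 USP4	downstream_gene_variant	3	29.33	10.97	0.55	0.19	FALSE
12	2800601	T	C	ENSGALG00000003738 ENSGALG00000003799	EMC3 USP4	downstream_gene_variant	2	32.5	2.12	0.22	0.01	FALSE
13	931843	T	C	ENSGALG00000000946	PFDN1	intron_variant	2	19.5	0.71	0.28	0.1	TRUE
13	931855	T	C	ENSGALG00000000946	PFDN1	intron_variant	3	22.67	4.73	0.65	0.09	TRUE
13	931888	T	C	ENSGALG00000000946	PFDN1	intron_variant	2	23.5	2.12	0.28	0.06	TRUE
13	10717577	T	C	ENSGALG00000003818	CYFIP2	missense_variant	2	40.5	17.68	0.27	0.08	TRUE
17	4705	T	C	ENSGALG00000014171	novel gene	intron_variant	3	45	6.56	0.18	0.03	FALSE
22	5274	T	C	-	-	intergenic_variant	2	16	0	0.7	0.18	FALSE
Z	27752047	A	G	-	-	intergenic_variant	3	29	4.58	0.23	0.06	FALSE
Z	27752050	A	G	-	-	intergenic_variant	3	28	4	0.84	0.05	FALSE
Z	27752217	A	G	-	-	intergenic_variant	2	31	4.21	0.57	0.01	FALSE
Z	30809802	T	C	-	-	intergenic_variant	2	23	7.1	0.25	0.05	FALSE
Z	30815599	T	C	ENSGALG00000005846	MPDZ	downstream_gene_variant	2	21.5	4.95	0.33	0.16	FALSE
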