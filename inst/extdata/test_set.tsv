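mutation	gene	zygosity_class	exp_hdl	exp_ldl	exp_tc	ref_hdl	ref_ldl	ref_tc	trained_hdl	trained_ldl	trained_tc	trained_hdl_sd	trained_ldl_sd	trained_tc_sd
1	LDLR	heterozygous	0.86	2.17	1.85	0.59	2.93	2.4	0.74	1.85	1.6	0.17	1.31	0.97
2	APOB	heterozygous	0.85	1.52	1.36	0.54	3.64	2.94	0.95	1.12	1.08	0.07	0.21	0.14
3	APOB	homozygous	1.12	2.24	1.97	0.54	3.64	2.94	0.72	1.95	1.67	NA	NA	NA
4	ABCA1	heterozygous	0.22	1.42	1.07	0.55	0.6	0.59	0.66	0.69	0.68	0.19	0.15	0.16
5	APOE	heterozygous	NA	NA	2.8	0.65	2.44	2.03	0.84	1.45	1.31	0.13	0.57	0.41
6	CETP	heterozygous	1.1	0.98	1.01	1.24	0.93	1	1.47	0.87	1.01	NA	NA	NA
7	LCAT	heterozygous	0.79	0.97	0.81	1.06	0.96	0.99	1.1	0.94	0.98	0.16	0.11	0.05
8	LCAT	homozygous	0.19	0.82	0.77	1.48	0.66	0.85	1	1	1	NA	NA	NA
9	DHCR7	heterozygous	NA	NA	0.2	1.13	0.37	0.54	1.13	0.37	0.54	0.01	0.04	0.03
10	CYP7A1	heterozygous	0.97	2.09	1.74	0.93	1.21	1.15	0.98	1.04	1.03	0.02	0.06	0.04
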