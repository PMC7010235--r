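dataset	gene	zygosity_class	patients	mutations	n_compound	rates
Autosomal Dominant Hypercholesterolemia	LDLR	heterozygous	13	9	0	5,7
Autosomal Dominant Hypercholesterolemia	APOB	heterozygous	7	1	0	5,7
Autosomal Dominant Hypercholesterolemia	APOB	homozygous	1	1	0	5,7
Autosomal Dominant Hypercholesterolemia	APOE	heterozygous	12	2	0	5,7
Other disease altering lipoprotein metabolism	ABCA1	heterozygous	7	3	1	8,16,17
Other disease altering lipoprotein metabolism	CETP	heterozygous	1	1	0	21
Other disease altering lipoprotein metabolism	LCAT	heterozygous	17	2	0	9
Other disease altering lipoprotein metabolism	LCAT	homozygous	7	4	0	9
Other disease altering lipoprotein metabolism	CYP7A1	heterozygous	2	1	0	18
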