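gene	zygosity_class	fmut_trained	fmut_reference
LDLR	heterozygous	0.58	0.38
APOB	heterozygous	0.9	0.31
APOB	homozygous	0.55	0.32
ABCA1	heterozygous	0.53	0.41
APOE	heterozygous	0.72	0.45
CETP	heterozygous	0.43	0.65
LCAT	heterozygous	0.48	0.62
LCAT	homozygous	1	0
DHCR7	any	0	0
CYP7A1	heterozygous	0.81	0.05
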