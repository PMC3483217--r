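screen	phenotype	screened	verified	genomewide_baseline
rnai_screen_A	long	16475	89	yes
rnai_screen_B	long	13300	29	yes
essential_gene_screen	long	2700	64	no
daf2_suppressor_screen	short	15718	159	no
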