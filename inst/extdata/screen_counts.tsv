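gene_set	phenotype	screened	preliminary	retested	verified
WLN	long	147	47	24	10
WLN	short	147	21	5	5
HLN	long	184	45	17	7
HLN	short	184	27	6	6
shared	long	43	9	4	2
shared	short	43	7	1	0
total	long	374	101	45	19
total	short	374	55	12	11
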