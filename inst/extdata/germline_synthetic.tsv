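gene	region	chain	aa_seq	nt_seq
TRBV19	V	TRB	CASSI	tgtgctagcagcatt
TRBV28	V	TRB	CASS	tgtgctagcagc
TRBV9	V	TRB	CASSV	tgtgctagcagcgtg
TRBV6-5	V	TRB	CASSY	tgtgctagcagctat
TRBV20-1	V	TRB	CSAR	tgtagcgctcgt
TRBJ2-7	J	TRB	SYEQYF	agctatgagcagtatttt
TRBJ2-1	J	TRB	NEQFF	aatgagcagtttttt
TRBJ1-2	J	TRB	YGYTF	tatggttatactttt
TRBJ2-3	J	TRB	DTQYF	gatactcagtatttt
TRAV12-2	V	TRA	CAVN	tgtgctgtgaat
TRAV29	V	TRA	CAAS	tgtgctgctagc
TRAV19	V	TRA	CALSE	tgtgctctgagcgag
TRAJ42	J	TRA	GSQGNLIF	ggtagccagggtaatctgattttt
TRAJ49	J	TRA	NTGNQFYF	aatactggtaatcagttttatttt
TRAJ33	J	TRA	DSNYQLIW	gatagcaattatcagctgatttgg
TRAJ26	J	TRA	YGQNFVF	tatggtcagaattttgtgttt
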