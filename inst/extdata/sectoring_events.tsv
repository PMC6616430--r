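stage	column	rows	half	codons	incoming	displaced	rule
columns	A	*	*		Val	Gly	columns sectored at anticodon position 2
columns	G	*	*		Ala	Gly	columns sectored at anticodon position 2
columns	U	*	*		Asp	Gly	columns sectored at anticodon position 2
split8	A	A,G	*		Leu	Val	purine rows ceded at anticodon position 3
split8	G	A,G	*		Pro	Ala	purine rows ceded at anticodon position 3
split8	C	A,G	*		Arg	Gly	purine rows ceded at anticodon position 3
split8	U	*	B		Glu	Asp	column 3 split at the wobble half
post_latch_16	A	U	*		Ile	Val	single-base resolution at anticodon position 3
post_latch_16	G	U	*		Thr	Ala	single-base resolution at anticodon position 3
post_latch_16	G	A	*		Ser	Pro	single-base resolution at anticodon position 3
post_latch_16	U	U	A		Asn	Asp	two-codon sectors in column 3
post_latch_16	U	G	A		His	Asp	two-codon sectors in column 3
post_latch_16	U	U	B		Lys	Glu	two-codon sectors in column 3
post_latch_16	U	G	B		Gln	Glu	two-codon sectors in column 3
completion	A	U	B	AUG	Met	Ile	single-codon occupancy of a mixed cell
completion	A	A	A		Phe	Leu	late addition to disfavored row 1
completion	U	A	A		Tyr	Asp	late addition to disfavored row 1
completion	U	A	B		STOP	Glu	stops confined to disfavored row 1
completion	C	U	A		Ser	Gly	Ser jump into favored column 4
completion	C	U	B		Arg	Gly	Arg gain in column 4
completion	C	A	A		Cys	Arg	late addition to disfavored row 1
completion	C	A	B	UGG	Trp	Arg	single-codon occupancy of a mixed cell
completion	C	A	B	UGA	STOP	Arg	stops confined to disfavored row 1
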