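pattern	te_type	clade
^SINE	SINE	None
^LINE/CR1	LINE	CR1
^LINE/R2	LINE	R2
^LINE/RTE	LINE	RTE
^LINE	LINE	OtherLINE
^LTR/ERVL	LTR	ERV3
^LTR/ERVK	LTR	ERV2
^LTR/ERV1	LTR	ERV1
^LTR/ERV2	LTR	ERV2
^LTR/ERV3	LTR	ERV3
^LTR	LTR	OtherLTR
^DNA	DNA	None
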