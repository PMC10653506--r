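name	pattern
fls_motif_1	PxxxIRxxxEQP
fls_motif_2	SxxTxLVP
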