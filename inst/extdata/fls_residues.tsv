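reference_id	position	expected	alternatives	role_tag
FLS_reference	68	G		folding
FLS_reference	75	H		folding
FLS_reference	207	P		folding
FLS_reference	221	H		ferrous iron binding
FLS_reference	223	D		ferrous iron binding
FLS_reference	261	G		folding
FLS_reference	277	H		ferrous iron binding
FLS_reference	287	R		2-oxoglutarate binding
FLS_reference	289	S		2-oxoglutarate binding
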