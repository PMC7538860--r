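optic_atrophy	smoke-test panel	NR2F1	AFG3L2
leber_congenital_amaurosis	smoke-test panel	RPE65	OTX2	LRAT
macular_degeneration	smoke-test panel	BEST1	RPE65
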