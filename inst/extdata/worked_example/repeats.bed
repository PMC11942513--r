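chrT	50	150	AluSyn	0	+
chrT	730	800	L1Syn	0	+
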