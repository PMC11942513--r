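contig	position	strand	gene_id	edit_class
chrT	400	+	GENE1	nonsynonymous
chrT	150	+	GENE1	nonsynonymous
chrT	700	+	GENE1	nonsynonymous
chrT	200	+	GENE1	nonsynonymous
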