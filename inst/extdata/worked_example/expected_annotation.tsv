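contig	position	strand	gene_id	edit_class	excluded	aggregate_class	per_transcript_classes	exon_start	exon_end	gq_found	gq_min_distance_bp	alu_overlap_bp	splice_associated	edit_enabled
chrT	400	+	GENE1	nonsynonymous	FALSE	internal_exon	GENE1.t1:internal_exon,GENE1.t2:non_exonic	350	500	TRUE	50	0	TRUE	FALSE
chrT	150	+	GENE1	nonsynonymous	FALSE	first_exon	GENE1.t1:first_exon,GENE1.t2:first_exon	100	250	FALSE	NA	50	FALSE	FALSE
chrT	700	+	GENE1	nonsynonymous	FALSE	last_exon	GENE1.t1:last_exon,GENE1.t2:last_exon	600	750	FALSE	NA	0	FALSE	TRUE
chrT	200	+	GENE1	nonsynonymous	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA
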