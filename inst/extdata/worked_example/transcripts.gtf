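chrT	quadedit	exon	101	250	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chrT	quadedit	exon	351	500	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chrT	quadedit	exon	601	750	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chrT	quadedit	exon	101	250	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
chrT	quadedit	exon	601	750	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
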