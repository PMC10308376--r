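chr1	toy	exon	1001	1100	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_type "protein_coding";
chr1	toy	exon	1301	1400	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_type "protein_coding";
chr1	toy	exon	1601	1700	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_type "protein_coding";
chr1	toy	exon	1001	1100	.	+	.	gene_id "G1"; transcript_id "G1.T2"; gene_type "protein_coding";
chr1	toy	exon	1601	1700	.	+	.	gene_id "G1"; transcript_id "G1.T2"; gene_type "protein_coding";
chr1	toy	exon	5001	5120	.	-	.	gene_id "G2"; transcript_id "G2.T1"; gene_type "lncRNA";
chr1	toy	exon	5301	5400	.	-	.	gene_id "G2"; transcript_id "G2.T1"; gene_type "lncRNA";
chr1	toy	exon	5001	5400	.	-	.	gene_id "G2"; transcript_id "G2.T2"; gene_type "lncRNA";
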