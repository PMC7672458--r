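## SYNTHETIC STAND-IN: gene architectures (spans, exon counts, mature lengths)
## reconstructed from published summary values; coordinates are NOT the real
## GENCODE v19 coordinates. For testing the metric-extraction path only.
chr12	SYNTHETIC	gene	6645000	6648884	.	+	.	gene_id "ENSG00000111640_SYN"; gene_type "protein_coding"; gene_name "GAPDH";
chr12	SYNTHETIC	transcript	6645000	6648884	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH";
chr12	SYNTHETIC	exon	6645000	6645105	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 1;
chr12	SYNTHETIC	exon	6645430	6645532	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 2;
chr12	SYNTHETIC	exon	6645857	6645970	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 3;
chr12	SYNTHETIC	exon	6646295	6646392	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 4;
chr12	SYNTHETIC	exon	6646717	6646832	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 5;
chr12	SYNTHETIC	exon	6647157	6647279	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 6;
chr12	SYNTHETIC	exon	6647604	6647737	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 7;
chr12	SYNTHETIC	exon	6648062	6648211	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 8;
chr12	SYNTHETIC	exon	6648537	6648884	.	+	.	gene_id "ENSG00000111640_SYN"; transcript_id "ENST_SYN_GAPDH"; gene_type "protein_coding"; gene_name "GAPDH"; exon_number 9;
chr20	SYNTHETIC	gene	34633000	34638377	.	-	.	gene_id "ENSG00000260032_SYN"; gene_type "lincRNA"; gene_name "NORAD";
chr20	SYNTHETIC	transcript	34633000	34638377	.	-	.	gene_id "ENSG00000260032_SYN"; transcript_id "ENST_SYN_NORAD"; gene_type "lincRNA"; gene_name "NORAD";
chr20	SYNTHETIC	exon	34633000	34638377	.	-	.	gene_id "ENSG00000260032_SYN"; transcript_id "ENST_SYN_NORAD"; gene_type "lincRNA"; gene_name "NORAD"; exon_number 1;
chr6	SYNTHETIC	gene	26017000	26017779	.	-	.	gene_id "ENSG00000124610_SYN"; gene_type "protein_coding"; gene_name "HIST1H1A";
chr6	SYNTHETIC	transcript	26017000	26017779	.	-	.	gene_id "ENSG00000124610_SYN"; transcript_id "ENST_SYN_HIST1H1A"; gene_type "protein_coding"; gene_name "HIST1H1A";
chr6	SYNTHETIC	exon	26017000	26017779	.	-	.	gene_id "ENSG00000124610_SYN"; transcript_id "ENST_SYN_HIST1H1A"; gene_type "protein_coding"; gene_name "HIST1H1A"; exon_number 1;
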