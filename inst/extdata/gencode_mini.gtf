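##description: miniature GENCODE-dialect annotation fixture (hand-enumerated)
chr1	HAVANA	gene	101	600	.	+	.	gene_id "ENSG00000000001.1"; gene_type "protein_coding"; gene_name "GENEA";
chr1	HAVANA	transcript	101	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; gene_name "GENEA"; tag "basic"; tag "CCDS";
chr1	HAVANA	exon	101	200	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; exon_number 1; tag "basic"; tag "CCDS";
chr1	HAVANA	exon	301	400	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; exon_number 2; tag "basic"; tag "CCDS";
chr1	HAVANA	exon	501	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; exon_number 3; tag "basic"; tag "CCDS";
chr1	HAVANA	CDS	350	400	.	+	0	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; tag "basic"; tag "CCDS";
chr1	HAVANA	CDS	501	550	.	+	0	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000101.3"; gene_type "protein_coding"; tag "basic"; tag "CCDS";
chr1	HAVANA	transcript	101	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000102.1"; gene_type "protein_coding"; gene_name "GENEA"; tag "basic";
chr1	HAVANA	exon	101	200	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000102.1"; gene_type "protein_coding"; exon_number 1; tag "basic";
chr1	HAVANA	exon	501	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000102.1"; gene_type "protein_coding"; exon_number 2; tag "basic";
chr1	HAVANA	transcript	101	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000103.1"; gene_type "protein_coding"; gene_name "GENEA";
chr1	HAVANA	exon	101	200	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000103.1"; gene_type "protein_coding"; exon_number 1;
chr1	HAVANA	exon	321	400	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000103.1"; gene_type "protein_coding"; exon_number 2;
chr1	HAVANA	exon	501	600	.	+	.	gene_id "ENSG00000000001.1"; transcript_id "ENST00000000103.1"; gene_type "protein_coding"; exon_number 3;
chr1	HAVANA	gene	1001	1500	.	-	.	gene_id "ENSG00000000002.2"; gene_type "protein_coding"; gene_name "GENEB";
chr1	HAVANA	transcript	1001	1500	.	-	.	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; gene_name "GENEB"; tag "basic";
chr1	HAVANA	exon	1401	1500	.	-	.	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; exon_number 1; tag "basic";
chr1	HAVANA	exon	1201	1300	.	-	.	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; exon_number 2; tag "basic";
chr1	HAVANA	exon	1001	1100	.	-	.	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; exon_number 3; tag "basic";
chr1	HAVANA	CDS	1401	1460	.	-	0	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; tag "basic";
chr1	HAVANA	CDS	1201	1300	.	-	0	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; tag "basic";
chr1	HAVANA	CDS	1061	1100	.	-	0	gene_id "ENSG00000000002.2"; transcript_id "ENST00000000201.1"; gene_type "protein_coding"; tag "basic";
chr2	HAVANA	gene	100	400	.	+	.	gene_id "ENSG00000000003.1"; gene_type "protein_coding"; gene_name "GENEC";
chr2	HAVANA	transcript	100	400	.	+	.	gene_id "ENSG00000000003.1"; transcript_id "ENST00000000301.1"; gene_type "protein_coding"; gene_name "GENEC"; tag "basic";
chr2	HAVANA	exon	100	200	.	+	.	gene_id "ENSG00000000003.1"; transcript_id "ENST00000000301.1"; gene_type "protein_coding"; exon_number 1; tag "basic";
chr2	HAVANA	exon	300	400	.	+	.	gene_id "ENSG00000000003.1"; transcript_id "ENST00000000301.1"; gene_type "protein_coding"; exon_number 2; tag "basic";
chr2	HAVANA	CDS	150	200	.	+	0	gene_id "ENSG00000000003.1"; transcript_id "ENST00000000301.1"; gene_type "protein_coding"; tag "basic";
chr2	HAVANA	CDS	300	350	.	+	0	gene_id "ENSG00000000003.1"; transcript_id "ENST00000000301.1"; gene_type "protein_coding"; tag "basic";
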