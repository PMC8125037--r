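chrom	pos	ref	alt	series	occurrences	source_label
1	11130641	G	A	SKCM	2	TCGA-SKCM
22	19219929	C	T	KIRP	2	TCGA-KIRP
11	129874521	G	A	other	1	fNTMC
22	41149147	C	T	SKCM	1	TCGA-SKCM
16	70663765	G	A	KIRP	1	TCGA-KIRP
16	70664615	T	C	SKCM	1	TCGA-SKCM
3	47084114	A	G	KIRC	3	TCGA-KIRC
3	47084114	A	G	KIRP	1	TCGA-KIRP
3	47084114	A	G	SKCM	1	TCGA-SKCM
3	47121407	T	C	SKCM	3	TCGA-SKCM
3	47121407	T	C	KIRP	1	TCGA-KIRP
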