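##fileformat=VCFv4.2
##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
1	100	rs1	A	G	.	PASS	R2=0.95	GT:DS	0/1:1.0	0/0:0.1	1/1:1.9
1	200	rs2	C	T	.	PASS	R2=0.35	GT:DS	0/0:0.0	./.:0.5	0/1:0.9
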