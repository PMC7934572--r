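##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
Chr01	101	v1	A	T	.	PASS	.	GT	0/0	0/1	1/1
Chr01	250	v2	G	GA	.	PASS	.	GT	0|1	./.	1/1
Chr01	333	v3	C	A,T	.	PASS	.	GT	1/2	0/1	0/0
Chr02	50	v4	T	C	.	PASS	.	GT	./1	1/0	0/0
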