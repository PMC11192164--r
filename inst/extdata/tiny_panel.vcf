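##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	IND1	IND2	IND3
chr1	100	.	A	G	.	PASS	.	GT	0/0	0/1	1/1
chr1	200	.	C	T	.	PASS	.	GT	0/1	./.	1|1
chr1	250	.	G	A,T	.	PASS	.	GT	0/1	0/2	1/1
chr1	300	.	T	C	.	PASS	.	GT	0/0	0/0	0/1
chr2	50	.	G	C	.	PASS	.	GT	1/1	1/1	1/1
chr2	80	.	GA	G	.	PASS	.	GT	0/1	0/0	0/0
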