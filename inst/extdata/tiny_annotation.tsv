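chrom	pos	ref	alt	effect
chr1	100	A	G	Missense variant
chr1	200	C	T	synonymous_variant
chr1	300	T	C	intergenic_region
chr2	50	G	C	splice_region_variant&intron_variant
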