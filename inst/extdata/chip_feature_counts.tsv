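feature	n_snps
exon	17957
intron	20506
five_prime	17102
three_prime	6488
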