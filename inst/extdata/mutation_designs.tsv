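line	design	generations
3B-87	vegetative_spore	1740
4B-87	vegetative_spore	1740
2B-52	vegetative_diploid	1040
3T-50	meiotic	1050
4T-50	meiotic	1050
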