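method	tetrads_germinated	colonies_typed	n_inter	n_self	n_multiple_tetrads	tetrads_two_typed
streak	100	200	168	32	14	100
microdissection	84	145	115	30	13	61
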