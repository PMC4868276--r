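07cb50cf  atchley_factors.tsv
63edddd5  aaindex_default.tsv
69f4288e  pseaac_scales.tsv
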