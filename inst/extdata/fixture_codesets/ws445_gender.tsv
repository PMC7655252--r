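0	unknown
1	male
2	female
9	unspecified
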