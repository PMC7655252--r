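1	fixture initial diagnosis
2	fixture revisit diagnosis
3	fixture confirmed diagnosis
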