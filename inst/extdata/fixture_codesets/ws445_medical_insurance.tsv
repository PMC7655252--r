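1	fixture urban employee scheme
2	fixture urban resident scheme
3	fixture rural cooperative scheme
4	fixture commercial insurance
9	fixture self-pay
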