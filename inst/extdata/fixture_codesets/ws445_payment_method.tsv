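01	fixture cash
02	fixture insurance card
03	fixture mobile payment
04	fixture bank transfer
99	fixture other
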