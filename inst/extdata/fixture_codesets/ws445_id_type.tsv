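01	fixture resident ID card
02	fixture passport
03	fixture military ID
99	fixture other
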