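01	fixture ethnicity A
02	fixture ethnicity B
03	fixture ethnicity C
04	fixture ethnicity D
05	fixture ethnicity E
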