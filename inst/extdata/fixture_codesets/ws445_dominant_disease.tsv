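DD01	fixture dominant disease 01
DD02	fixture dominant disease 02
DD03	fixture dominant disease 03
DD04	fixture dominant disease 04
DD05	fixture dominant disease 05
DD06	fixture dominant disease 06
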