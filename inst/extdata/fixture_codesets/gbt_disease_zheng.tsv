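DD01	fixture classified disease 01
DD02	fixture classified disease 02
DD03	fixture classified disease 03
DD04	fixture classified disease 04
DD05	fixture classified disease 05
DD06	fixture classified disease 06
ZB-001	fixture zheng class 001
ZB-002	fixture zheng class 002
ZB-003	fixture zheng class 003
ZB-004	fixture zheng class 004
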