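DIS-001	fixture disease 001
DIS-002	fixture disease 002
DIS-003	fixture disease 003
DIS-004	fixture disease 004
DIS-005	fixture disease 005
DIS-006	fixture disease 006
DIS-007	fixture disease 007
DIS-008	fixture disease 008
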