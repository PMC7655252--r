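TM-001	fixture therapeutic method 001
TM-002	fixture therapeutic method 002
TM-003	fixture therapeutic method 003
TM-004	fixture therapeutic method 004
TM-005	fixture therapeutic method 005
TM-006	fixture therapeutic method 006
TM-007	fixture therapeutic method 007
TM-008	fixture therapeutic method 008
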