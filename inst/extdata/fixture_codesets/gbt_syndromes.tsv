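SYN-001	fixture syndrome 001
SYN-002	fixture syndrome 002
SYN-003	fixture syndrome 003
SYN-004	fixture syndrome 004
SYN-005	fixture syndrome 005
SYN-006	fixture syndrome 006
SYN-007	fixture syndrome 007
SYN-008	fixture syndrome 008
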