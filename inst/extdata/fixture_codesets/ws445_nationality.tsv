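CHN	fixture nationality CHN
JPN	fixture nationality JPN
KOR	fixture nationality KOR
SGP	fixture nationality SGP
THA	fixture nationality THA
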