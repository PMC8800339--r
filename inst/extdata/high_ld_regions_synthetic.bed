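1	100000	200000
2	500000	650000
6	250000	400000
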