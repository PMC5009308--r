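# synthetic 6-disease toy ontology (one root, two branches)
d1	C01
d2	C01.100
d3	C01.200
d4	C01.100.050
d5	C01.200.050
d6	C01.200.100
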