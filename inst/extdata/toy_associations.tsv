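# synthetic toy associations: 2 miRNAs over the 6-disease ontology
m1	d1
m1	d2
m1	d4
m2	d3
m2	d5
m2	d6
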