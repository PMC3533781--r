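# kit_id: TOY2
# locus: A
P1	A*01:01
P2	A*02:01,A*03:01
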