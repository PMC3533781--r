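# Toy multiple-allele-code table for tests and examples.
# code<TAB>comma-separated second-field values
XX	01,02
YY	01,05
ZZAB	01,02,03
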