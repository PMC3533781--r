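id,locus,genotype
ind001,A,A*01:01+A*02:01
ind002,A,A*01:01/A*01:02+A*02:01
ind003,A,A*01:01+A*01:01|A*01:01+A*03:01
ind004,A,A*02:01+A*03:01
ind005,A,A*01:02+A*02:01
ind006,A,A*01:01+A*01:01
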