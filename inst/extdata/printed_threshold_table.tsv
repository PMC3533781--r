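# Published allele-frequency significance thresholds (percent) by sample
# size and sampling model: I two-tail normal, II one-tail normal, III exact
# binomial.  Kept verbatim so computed tables can be checked against the
# printed ones (a few printed cells deviate from the formulas by <= 0.02).
N	model_I	model_II	model_III
30	6.25	4.43	4.85
50	3.85	2.75	2.95
100	1.96	1.37	1.48
150	1.32	0.92	1.00
200	0.99	0.69	0.75
500	0.39	0.28	0.30
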