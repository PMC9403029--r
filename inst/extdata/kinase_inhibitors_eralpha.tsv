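id	score_pos	score_neg	docking_score	significance
sunitinib	0.52	0.74	-154.7	7%
dasatinib	0.51	0.75	-52.83	8%
pazopanib	0.57	0.76	-43.23	3%
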