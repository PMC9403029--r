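id	score_pos	score_neg	docking_score	significance
PDE4B	0.69	0.83	-167.63	<1%
SRC	0.70	1.17	-92.22	2%
HLA-B	0.67	0.86	-85.80	2%
HLA-A	0.69	0.75	-73.87	3%
MAPK1	0.65	0.99	-72.66	4%
MAPKAPK2	0.64	0.86	-50.03	9%
QPRT	0.65	0.76	-40.77	9%
FLG	0.70	0.72	-23.11	11%
FECH	0.68	0.90	-13.99	14%
PKCeta	0.58	0.78	-11.71	14%
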