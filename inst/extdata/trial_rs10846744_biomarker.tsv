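study	row	stratum	maf	n	beta	se	p
STABILITY	stratum	Caucasian	0.17	9448	4.15	0.67	5.52e-10
STABILITY	stratum	African-American	0.53	254	4.78	4.12	0.247
STABILITY	stratum	Asian	0.64	1257	3.18	2.06	0.122
STABILITY	stratum	Other	0.25	1637	2.1	1.63	0.196
STABILITY	pooled	All	0.24	12596	3.57	0.59	1.49e-09
STABILITY	meta	All	NA	12596	3.82	0.59	7.22e-11
SOLID-TIMI 52	stratum	Caucasian	0.16	7503	3.305	0.76	1.51e-05
SOLID-TIMI 52	stratum	African-American	0.59	185	5.823	4.44	0.191
SOLID-TIMI 52	stratum	Asian	0.62	408	-2.661	3.51	0.449
SOLID-TIMI 52	stratum	Other	0.27	1303	0.977	1.63	0.55
SOLID-TIMI 52	pooled	All	0.21	9399	2.581	0.67	1.18e-04
SOLID-TIMI 52	meta	All	NA	9399	2.209	1.16	5.68e-02
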