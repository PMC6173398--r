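trait	stratum	n	beta	se	p
lppla2_mass	Caucasian	1842	2.934	1.665	0.08
lppla2_mass	African-American	1155	-1.252	1.728	0.47
lppla2_mass	Hispanic	1130	3.224	1.561	0.04
lppla2_mass	Chinese-American	602	1.781	2.358	0.45
lppla2_activity	Caucasian	1861	1.541	1.356	0.26
lppla2_activity	African-American	1202	1.469	1.366	0.28
lppla2_activity	Hispanic	1155	3.573	1.384	0.01
lppla2_activity	Chinese-American	603	4.328	2.206	0.05
hscrp	Caucasian	2452	0.009	0.042	0.84
hscrp	African-American	1949	0.001	0.039	0.99
hscrp	Hispanic	1739	0.055	0.039	0.17
hscrp	Chinese-American	701	0.022	0.055	0.69
homocysteine	Caucasian	2305	-0.007	0.010	0.46
homocysteine	African-American	1585	-0.011	0.010	0.26
homocysteine	Hispanic	1418	-0.014	0.010	0.19
homocysteine	Chinese-American	703	-0.019	0.013	0.16
il6	Caucasian	2277	-0.010	0.025	0.68
il6	African-American	1530	-0.005	0.025	0.85
il6	Hispanic	1387	0.007	0.025	0.77
il6	Chinese-American	695	0.013	0.036	0.73
eselectin	Caucasian	551	-0.482	1.598	0.76
eselectin	African-American	223	-0.679	2.406	0.78
eselectin	Hispanic	270	-1.478	2.418	0.54
eselectin	Chinese-American	93	-0.763	3.843	0.84
pai1	Caucasian	398	0.033	0.094	0.73
pai1	African-American	180	0.159	0.095	0.10
pai1	Hispanic	216	-0.046	0.085	0.59
pai1	Chinese-American	90	-0.092	0.116	0.43
sicam1	Caucasian	1249	5.421	3.252	0.10
sicam1	African-American	452	-6.193	6.483	0.34
sicam1	Hispanic	600	-3.829	4.686	0.41
sicam1	Chinese-American	260	-3.125	5.187	0.55
ldl_particles	Caucasian	2311	8.388	12.148	0.49
ldl_particles	African-American	1585	9.345	12.942	0.47
ldl_particles	Hispanic	1418	41.361	13.901	0.003
ldl_particles	Chinese-American	705	12.628	17.364	0.47
ala	Caucasian	2247	0.034	0.013	0.01
ala	African-American	1525	0.008	0.013	0.56
ala	Hispanic	1373	-0.008	0.015	0.58
ala	Chinese-American	698	0.014	0.021	0.49
epa	Caucasian	1600	0.041	0.025	0.09
epa	African-American	891	0.009	0.027	0.74
epa	Hispanic	692	0.002	0.029	0.94
epa	Chinese-American	51	-0.097	0.147	0.51
dha	Caucasian	2247	0.088	0.045	0.05
dha	African-American	1522	0.039	0.049	0.42
dha	Hispanic	1369	0.051	0.042	0.23
dha	Chinese-American	696	0.091	0.078	0.24
dpa	Caucasian	2244	0.000	0.008	0.97
dpa	African-American	1521	0.018	0.008	0.03
dpa	Hispanic	1370	0.009	0.008	0.29
dpa	Chinese-American	694	0.011	0.013	0.43
la	Caucasian	2254	-0.049	0.113	0.67
la	African-American	1530	-0.084	0.105	0.42
la	Hispanic	1376	-0.129	0.121	0.29
la	Chinese-American	697	-0.290	0.191	0.13
gla	Caucasian	2238	0.000	0.002	0.98
gla	African-American	1525	0.003	0.002	0.10
gla	Hispanic	1368	0.000	0.002	0.82
gla	Chinese-American	691	0.003	0.003	0.35
dgla	Caucasian	2252	-0.010	0.031	0.75
dgla	African-American	1526	0.004	0.025	0.88
dgla	Hispanic	1377	0.031	0.035	0.38
dgla	Chinese-American	699	0.051	0.044	0.24
aa	Caucasian	2255	-0.041	0.089	0.64
aa	African-American	1527	-0.071	0.089	0.43
aa	Hispanic	1375	0.105	0.096	0.28
aa	Chinese-American	698	-0.007	0.118	0.95
aa_la	Caucasian	2246	0.000	0.006	0.10
aa_la	African-American	1524	0.000	0.007	0.97
aa_la	Hispanic	1369	0.012	0.007	0.06
aa_la	Chinese-American	696	0.005	0.008	0.48
gla_la	Caucasian	2244	0.000	0.001	0.81
gla_la	African-American	1524	0.001	0.001	0.08
gla_la	Hispanic	1372	0.000	0.001	0.64
gla_la	Chinese-American	696	0.000	0.001	0.65
dgla_gla	Caucasian	2250	-0.011	0.016	0.51
dgla_gla	African-American	1525	-0.025	0.015	0.09
dgla_gla	Hispanic	1374	0.008	0.017	0.63
dgla_gla	Chinese-American	698	0.009	0.025	0.73
aa_dgla	Caucasian	2251	-0.002	0.012	0.86
aa_dgla	African-American	1527	-0.008	0.012	0.51
aa_dgla	Hispanic	1373	0.005	0.012	0.70
aa_dgla	Chinese-American	697	-0.020	0.019	0.29
dgla_la	Caucasian	2248	0.000	0.002	0.94
dgla_la	African-American	1525	0.001	0.002	0.46
dgla_la	Hispanic	1371	0.002	0.002	0.35
dgla_la	Chinese-American	697	0.004	0.002	0.10
dha_ala	Caucasian	2250	-0.010	0.018	0.58
dha_ala	African-American	1529	0.001	0.018	0.95
dha_ala	Hispanic	1375	0.025	0.021	0.23
dha_ala	Chinese-American	698	-0.011	0.027	0.69
epa_ala	Caucasian	2248	-0.002	0.022	0.94
epa_ala	African-American	1525	0.025	0.023	0.27
epa_ala	Hispanic	1370	0.032	0.023	0.16
epa_ala	Chinese-American	697	0.044	0.042	0.30
dpa_epa	Caucasian	2248	-0.020	0.009	0.03
dpa_epa	African-American	1527	-0.012	0.010	0.20
dpa_epa	Hispanic	1376	-0.010	0.010	0.33
dpa_epa	Chinese-American	697	-0.025	0.015	0.11
dha_epa	Caucasian	2248	-0.024	0.017	0.17
dha_epa	African-American	1526	-0.030	0.019	0.12
dha_epa	Hispanic	1374	-0.022	0.022	0.31
dha_epa	Chinese-American	696	-0.051	0.034	0.148
dha_dpa	Caucasian	2253	0.023	0.012	0.06
dha_dpa	African-American	1526	-0.009	0.012	0.43
dha_dpa	Hispanic	1376	0.004	0.013	0.77
dha_dpa	Chinese-American	697	-0.001	0.015	0.92
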