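trait	beta	se	p	log10_bf	I2	het_p
lppla2_mass	1.775	0.882	0.04	0.30	32.0	0.22
lppla2_activity	2.424	0.744	0.001	1.69	0.0	0.50
hscrp	0.022	0.021	0.31	-0.25	0.0	0.78
homocysteine	-0.012	0.005	0.03	0.69	0.0	0.90
il6	-0.001	0.013	0.97	-0.80	0.0	0.94
eselectin	-0.760	1.116	0.50	-0.40	0.0	0.99
pai1	0.019	0.048	0.70	-0.40	18.8	0.30
sicam1	-0.371	2.230	0.87	-0.35	36.1	0.20
ldl_particles	17.354	6.862	0.01	1.16	24.7	0.26
ala	0.013	0.007	0.08	0.23	36.4	0.19
epa	0.019	0.015	0.23	-0.14	0.0	0.60
dha	0.063	0.025	0.01	0.86	0.0	0.86
dpa	0.009	0.004	0.04	0.53	0.0	0.47
la	-0.107	0.062	0.08	0.24	0.0	0.74
gla	0.001	0.001	0.24	-0.35	0.0	0.60
dgla	0.012	0.016	0.45	-0.46	0.0	0.64
aa	-0.008	0.048	0.88	-0.50	0.0	0.57
aa_la	0.004	0.003	0.20	-0.19	0.0	0.55
gla_la	0.001	0.000	0.12	-0.54	0.0	0.86
dgla_gla	-0.009	0.009	0.33	-0.28	0.0	0.45
aa_dgla	-0.004	0.007	0.54	-1.09	0.0	0.70
dgla_la	0.002	0.001	0.11	0.22	0.0	0.53
dha_ala	-0.002	0.010	0.87	-0.40	0.0	0.60
epa_ala	0.020	0.012	0.10	-0.54	0.0	0.65
dpa_epa	-0.016	0.005	0.002	1.52	0.0	0.78
dha_epa	-0.028	0.011	0.008	1.09	0.0	0.90
dha_dpa	0.004	0.006	0.52	-0.50	20.6	0.29
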