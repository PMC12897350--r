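marker	intercept	sd_error	mae	r	loo_residual_variance_pct	loo_residual_sd	loo_explained_variance_pct	loo_mean_prediction_error
acidity	0.39	0.04	0.03	0.96	10.79	0.05	89.21	0.04
k232	2.55	0.19	0.14	0.97	7.83	0.21	92.17	0.17
k270	0.74	0.13	0.09	0.98	6.48	0.15	93.52	0.11
delta_k	0.06951	0.02	0.01	0.97	7.44	0.02	92.56	0.02
pv	13.05556	1.73	1.22	0.94	18.33	1.97	81.67	1.57
anv	18.47035	5.25	3.34	0.96	13.48	6.17	86.52	4.35
totox	44.56894	10.72	7.37	0.90	27.36	11.99	72.64	8.88
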