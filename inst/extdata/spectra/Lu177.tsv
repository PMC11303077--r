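#name Lu177
#half_life_days 6.647
#electron_energy_per_decay_keV 147.9
#beta_endpoint_keV Lu177 498
energy_keV	yield_per_decay	category	nuclide_part
0.119	0.975	AE	Lu177
7	0.1448	AE	Lu177
6.2	0.0034	CE	Lu177
47.6	0.0437	CE	Lu177
101.9	0.085	CE	Lu177
110.7	0.0196	CE	Lu177
143.1	0.003	CE	Lu177
197.2	8e-04	CE	Lu177
133.3	0.99963	BETA_MEAN	Lu177
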