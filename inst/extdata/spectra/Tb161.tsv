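#name Tb161
#half_life_days 6.964
#electron_energy_per_decay_keV 202.5
#beta_endpoint_keV Tb161 593
energy_keV	yield_per_decay	category	nuclide_part
0.119	9.555	AE	Tb161
5.4	1.445	AE	Tb161
3.3	0.3	CE	Tb161
16.7	0.39	CE	Tb161
20.8	0.065	CE	Tb161
23.6	0.096	CE	Tb161
40.1	0.28	CE	Tb161
47	0.07	CE	Tb161
65.7	0.175	CE	Tb161
72.7	0.022	CE	Tb161
98.3	0.005	CE	Tb161
154.3	1.00021	BETA_MEAN	Tb161
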