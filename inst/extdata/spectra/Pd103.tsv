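#name Pd103
#half_life_days 16.991
#electron_energy_per_decay_keV 5.82
energy_keV	yield_per_decay	category	nuclide_part
0.119	5.937	AE	Pd103
2.325	1.4	AE	Pd103
16.9	0.068	AE	Pd103
19.77	0.031	AE	Pd103
22.3	0.0043	AE	Pd103
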