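#name Rh103m
#half_life_days 0.039
#electron_energy_per_decay_keV 37.69
energy_keV	yield_per_decay	category	nuclide_part
0.119	5.099	AE	Rh103m
2.325	0.762	AE	Rh103m
16.9	0.0125	AE	Rh103m
19.77	0.0057	AE	Rh103m
22.3	8e-04	AE	Rh103m
16.6	0.0941	CE	Rh103m
36.36	0.725	CE	Rh103m
39.1	0.153	CE	Rh103m
39.75	0.0268	CE	Rh103m
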