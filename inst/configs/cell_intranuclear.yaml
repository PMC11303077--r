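nuclide: Pd103_series
geometry:
  kind: cell
distribution: nucleus
histories: 30000.0
seed: 1
normalization:
  mode: energy_density
  energy_density_MeV_um3: 1.0
labeling_mask: ~
settings:
  cutoff_eV: 7.4
  sampling: poisson
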