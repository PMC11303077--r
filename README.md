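# celldosim

Monte Carlo cellular dosimetry for Auger- and conversion-electron emitting
radionuclides in R.

## The problem

Targeted radionuclide therapy aimed at disseminated tumor cells has to
deposit electron energy *inside* single 10–15 µm cells and small cell
clusters. Conventional beta emitters (¹⁷⁷Lu) spread their energy over
hundreds of microns, so nearly all of it escapes a cell-sized target.
¹⁰³Pd decays by electron capture (T½ = 16.991 d) to ¹⁰³ᵐRh (T½ = 56 min),
which de-excites by internal conversion: the series emits ~13 Auger
electrons plus ~1 conversion electron per decay, 43.51 keV of electron
energy in total, 99% of which is absorbed within 25 µm of the decay site.
`celldosim` quantifies what that means at the cellular scale:

* **Emission schemes** (`build_scheme()`): per-decay electron emission
  models for `Pd103`, `Rh103m`, the combined `Pd103_series`, `Lu177` and
  `Tb161`, reconstructed from published per-decay statistics (energies per
  decay, Auger counts, weighted averages, beta mean energies) and
  revalidated by `validate_scheme()`.
* **Electron transport** (`transport_electron()`, `radial_profile()`):
  event-by-event track structure in liquid water down to a 7.4 eV cutoff
  (binary-encounter-Bethe ionization, discrete excitations,
  screened-Rutherford elastic scattering), with a condensed-history tier
  above 10 keV (restricted Bethe stopping, explicit Møller delta rays).
* **Geometries** (`sphere_model()`, `cell_model()`, `cluster_model()`,
  `multicluster_model()`): water spheres from 1 to 1000 µm; a 14-µm cell
  with 10-µm nucleus and 10-nm membrane; a 19-cell cluster (central cell,
  6 touching neighbors, 12 second-shell neighbors); seven clusters with one
  unlabeled.
* **Dosimetry** (`run_scenario()`, `dose_table()`, `s_value()`,
  `self_cross_split()`, `category_contribution()`): compartment doses split
  by source cell, decay-series part and emission category, with batch
  standard errors; per-decay S-values or the 1 MeV/µm³ energy-density
  normalization (23.0 decays/µm³ for the ¹⁰³Pd series; 160.2 Gy at full
  absorption; 1436.8 MeV per labeled cell).
* **Scenario planning** (`scenario_config()`, `run_heterogeneous_cluster()`,
  `run_dual_targeting()`, `decays_for_dose()`, `initial_activity()`):
  declarative YAML/JSON configs, non-uniform labeling, dual-targeting, and
  closed-form decay/activity requirements for a target nuclear dose.

## A worked example

Dose to a single 14-µm tumor cell carrying ¹⁰³Pd(/¹⁰³ᵐRh) on its surface,
normalized to 1436.8 MeV released:

```r
library(celldosim)

cfg <- scenario_config("Pd103_series", list(kind = "cell"),
                       "cell_surface", histories = 2e4, seed = 1)
tally <- run_scenario(cfg)
print(dose_table(tally)[, c("compartment", "dose_Gy", "stderr_Gy",
                            "AE_fraction", "Rh103m_Gy")], digits = 3)
```

```
  compartment dose_Gy stderr_Gy AE_fraction Rh103m_Gy
1     nucleus    14.9     0.269       0.154      12.8
2   cytoplasm    33.0     0.248       0.468      22.2
3    membrane   950.4     2.854       0.965     416.1
```

The membrane — a 10-nm, 6.15-fg shell directly under the source — receives
~950 Gy, 96% of it from Auger electrons, while the nucleus 2 µm away
receives ~15 Gy, mostly from the 16.6–39.8 keV conversion electrons of
¹⁰³ᵐRh (the `Rh103m_Gy` column). That contrast is the core argument for
this decay series: very high local doses with a 25-µm sphere of action.

How many decays must a cell host for its nucleus to reach the 7.3 Gy
reference dose (survival < 1%), and what initial activity is that?

```r
n <- decays_for_dose(7.3, 15.6, build_scheme("Pd103_series"))
c(decays = n, mBq = 1000 * initial_activity(n, 16.991))
```

```
      decays          mBq 
15452.740013     7.296226 
```

About 15 400 decays, i.e. ~7.3 mBq of ¹⁰³Pd per cell at uptake time.

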