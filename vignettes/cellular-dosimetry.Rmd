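---
title: "Cellular dosimetry of Auger- and conversion-electron emitters with celldosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular dosimetry of Auger- and conversion-electron emitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radionuclide therapy of disseminated tumor cells hinges on depositing
electron energy inside single cells and small cell clusters. Beta emitters
such as ¹⁷⁷Lu release most of their energy over hundreds of microns, so in a
14-µm cell almost all of it escapes. Auger-electron (AE) and
conversion-electron (CE) emitters concentrate their energy over nanometers
to a few tens of microns. `celldosim` simulates this regime: it samples the
per-decay electron emissions of ¹⁰³Pd, ¹⁰³ᵐRh, the combined
¹⁰³Pd(/¹⁰³ᵐRh) decay series, ¹⁷⁷Lu and ¹⁶¹Tb, transports every electron
through liquid water event by event down to 7.4 eV, and scores absorbed
dose per cell compartment (nucleus, cytoplasm, 10-nm membrane) in spheres,
a single 14-µm cell, a 19-cell cluster and a seven-cluster tumor model.

## Emission schemes

Published decay tables print per-decay summaries — total electron energy
per decay (43.51 keV for the ¹⁰³Pd series, 5.82 for ¹⁰³Pd alone, 37.69 for
¹⁰³ᵐRh, 147.9 for ¹⁷⁷Lu, 202.5 for ¹⁶¹Tb), AE counts, energy ranges and
yield-weighted averages — rather than full line lists. The built-in schemes
reconstruct discrete spectra from that structure:

* a low-energy AE group at 119 eV (M/N-shell Auger cascades),
* an L-Auger group at 2.325 keV,
* K-Auger lines at 16.9, 19.77 and 22.3 keV whose yields follow standard
  rhodium-atom relaxation estimates (K-vacancy rate times one minus the K
  fluorescence yield), and
* for ¹⁰³ᵐRh, conversion-electron lines at 16.6, 36.36, 39.10 and
  39.75 keV.

The yields of the two low AE groups are solved per nuclide so that the AE
energy per decay and the AE count match the published table exactly; the CE
yields are solved from the CE energy per decay (34.97 keV) and the weighted
mean (35 keV) with standard L:M:N internal-conversion ratios. The solved
CE-K yield (0.094) agrees with nuclear-data values, which supports the
construction. One caveat is documented rather than hidden: the printed
"two main AE groups" (6.35 electrons at 119 eV, 0.92 at 2325 eV) do not by
themselves close the printed totals (13.3 AE carrying 8.54 keV per series
decay), so the per-nuclide totals are taken as the binding constraints and
the group counts come out larger than the printed two-group description.

Beta continua (¹⁷⁷Lu, ¹⁶¹Tb) use an allowed-transition phase-space shape
rescaled so the sampled mean equals the printed mean energy (133.3 and
154.3 keV); the endpoints (498 and 593 keV) are configurable parameters
since only the means are published. `validate_scheme()` re-checks every
bookkeeping invariant and `write_spectrum_tsv()` exchanges spectra as
columnar text, so a user with a full published line list can load it
directly.

Per-decay emission numbers are Poisson with the line yield as expectation
(AE multiplicities are treated as independent emissions); an
expected-value mode emits each line once with its yield as a statistical
weight for variance-free kernel work. Each ¹⁰³ᵐRh decay occurs at the same
spatial site as its parent ¹⁰³Pd decay, per the one-decay-series-per-site
assumption; both parts are tagged so their dose contributions remain
separable.

## Electron transport

Transport runs in unbounded liquid water (unit density) with two tiers that
share one elastic-scattering machinery:

* **Event by event below 10 keV.** Ionization uses the
  binary-encounter-Bethe (BEB) model for the five water orbitals (binding
  energies 12.62–539.7 eV); secondary-electron energies are sampled from
  the BEB differential cross section by rejection, the binding energy is
  deposited at the collision site and every secondary above the cutoff is
  tracked in turn. Five discrete excitation channels (8.22–13.77 eV) with a
  Born-like energy dependence complete the inelastic model.
* **Condensed history above 10 keV.** Between discrete events the electron
  loses energy continuously at the restricted Bethe collision stopping
  power (mean excitation energy 78 eV); each step's continuous loss is
  deposited at a uniformly random point of the step segment, which keeps
  mean doses unbiased even for targets as thin as the 10-nm membrane.
  Møller delta rays above 1 keV are produced explicitly and handed to the
  event-by-event tier; the restricted stopping power is the Bethe total
  minus the closed-form Møller energy-loss moment above that threshold.

Elastic scattering is sampled discretely in both tiers from
screened-Rutherford cross sections with Molière screening, summed over the
two hydrogens and the oxygen of each molecule. We deliberately use
discrete elastic events rather than a Gaussian multiple-scattering lump in
the condensed tier: elastic mean free paths at 10–600 keV (tens of nm to
µm) make this affordable, and it avoids small-angle approximations in
exactly the 15–40 keV window that drives cell-to-cell cross-dose.

Sub-excitation electrons — below the 7.4 eV cutoff or below the lowest
excitation channel — deposit their residual energy locally; their sub-nm
thermalization displacement is not modelled. Bremsstrahlung (sub-percent
below ~600 keV) and the density-effect correction are neglected. Photons
are out of scope throughout.

Numerical checks built into the test suite: energy is conserved exactly
per history; the stopping power at 10–100 keV lies within a few percent of
standard water values; the track extent of monoenergetic electrons
approaches the package's own CSDA integral `csda_range()` (the stated
independent oracle), with elastic detours shortening the mean penetration
to ~0.7 of the path length, consistent with practical-range systematics.

**Calibration, done once.** The single excitation-scale constant was fixed
so that the transported mean penetration of the 2.3 keV Auger group is
~148 nm, matching the ~146 nm figure quoted for that group, while keeping
the 1–10 keV stopping power standard. With screened-Rutherford elastic
scattering the 119 eV group then penetrates ~2.4 nm rather than the quoted
~6.4 nm; that anchor is unreachable in this elastic model (sub-nm elastic
mean free paths), and since both figures are far below the 10-nm membrane
thickness, compartment doses are insensitive to the difference. This is a
known limitation, not a tunable.

**Reproducibility.** Every history owns a counter-based random stream keyed
by (seed, source-cell index, history index), so a cluster tally equals the
sum of the corresponding single-labeled-cell tallies run with the same
seed, entry by entry — an identity the tests assert exactly.

## Geometries

The cell is a 14-µm sphere with a centered 10-µm nucleus (36% of the cell
volume) and a 10-nm membrane shell; compartment intervals are closed on
their outer radius (r = 7 µm belongs to the membrane, r = 5 µm to the
nucleus). "Cell surface" sources sit exactly on the outer membrane sphere.

**The 19-cell cluster is three-dimensional.** The published description —
a central cell, six immediate neighbors and a second layer of twelve — is
realized here as the first and second coordination shells of a cubic
lattice: six face neighbors at 14 µm (touching) and twelve edge neighbors
at 14√2 ≈ 19.8 µm, each touching four first-shell cells. The planar
hexagonal alternative (second ring at 24.2 and 28 µm) was rejected on
quantitative grounds: with a transport kernel independently validated
against published sphere S-values at every diameter from 1 to 1000 µm, the
planar layout underpredicts the central cell's cross-dose by ~35%, while
the cubic shells reproduce the central/first/second cross-dose pattern of
the published cluster table within a few percent. The cubic reading also
makes the labeled clusters of the multi-cluster model behave as isolated
clusters, as published. Cells of a given shell are equivalent by symmetry;
doses are reported per cell and agree within batch error across a shell.

The multi-cluster model places seven clusters in a planar flower at a
60-µm pitch with one peripheral cluster unlabeled; the resulting distance
from the unlabeled central cell's nucleus surface to the nearest labeled
cell surface is ≈28 µm (and the constructor enforces ≥28 µm for any user
layout). Whether that published "28 µm" meant nucleus-surface-to-surface
or another convention is ambiguous; this package fixes the convention
stated above and exposes the pitch as a parameter.

The four unlabeled cells of the heterogeneity scenarios are not identified
in the source material; the shipped default unlabels cell 3 (first shell)
and cells 9, 13, 18 (second shell), and every heterogeneity result is
flagged as mask-dependent. The mask is a required, serializable
configuration field.

## Dose accounting and normalization

Tallies accumulate energy per (target cell, compartment), split by source
cell, decay-series part (¹⁰³Pd vs ¹⁰³ᵐRh) and emission category (AE, CE,
beta), in 10 independent history batches for standard errors. Parts and
categories sum to totals exactly — bookkeeping, not statistics.

Two normalizations are provided. Per-decay tallies give S-values
(Gy·Bq⁻¹·s⁻¹). Energy-density tallies follow the 1 MeV/µm³ convention:
1000/E_decay decays per µm³ (23.0 for the ¹⁰³Pd series, 6.76 for ¹⁷⁷Lu,
4.94 for ¹⁶¹Tb), i.e. 1436.8 MeV released per labeled 14-µm cell, with
160.2 Gy as the full-absorption bound. The number of decays per labeled
cell (1436.8 MeV / E_decay ≈ 33 022 for the series) is applied as an exact
deterministic scale factor rather than by stochastically rounding decay
counts — identical in expectation and lower variance. Energy escaping the
geometry is tallied explicitly, so absorbed fractions are auditable:
deposited-plus-escaped equals released to machine precision.

Membrane doses use analog scoring; the 10-nm shell has a mass of only
6.15 fg, so membrane scenarios should use ≥10⁴–10⁵ source decays (the
random-point-on-segment deposition of condensed-history steps keeps the
estimate unbiased at any step length).

## Problem sizes

Defaults used by the shipped tests and the acceptance script, chosen to
keep Monte Carlo standard errors a few times smaller than the 10–15%
transport-model tolerance: 10⁴–2×10⁴ decays for point-source profiles and
spheres, 3×10⁴ for the single cell, 4×10³ per cell for the 19-cell cluster,
and 8×10² per labeled cell (9.1×10⁴ total) for the multi-cluster model. At
these sizes the full acceptance recomputation runs in a few minutes on one
CPU; all sizes scale linearly if tighter errors are wanted.

## Activity planning

`decays_for_dose()` inverts the per-cell normalization: with a tabulated
dose D per 1436.8 MeV released and a target nuclear dose D*, the required
decays are (1436.8 MeV / E_decay) × D*/D. `initial_activity()` converts
decays to the initial activity A₀ = N·ln2/T½ under instant uptake and
complete in-situ decay. For the 7.3 Gy nuclear-dose reference point with a
surface-bound ¹⁰³Pd(/¹⁰³ᵐRh) label this gives ≈1.54×10⁴ decays and
≈7.3 mBq per cell.

## What the synthetic spectra do and do not establish

The schemes emulate per-decay summary statistics, not evaluated
nuclear-data files: the discrete line lists are reconstructions constrained
by printed totals, so any observable that depends only on those totals and
on µm-scale transport (sphere doses, compartment doses, R99 radii,
self/cross splits) is meaningful, while nm-scale observables that depend on
the detailed sub-keV cascade (e.g. DNA-scale clustering of ionizations)
are outside what passing tests demonstrate. Likewise the transport model
is a desk-scale reimplementation with published-physics components; its
agreement with the reference results is bounded by the stated 10–15%
tolerances, not bit-identical to any particular production code. Real
cells vary in size and nucleus position; this package fixes the 14/10-µm
concentric geometry of the study it models.

## A worked example

```{r example}
library(celldosim)

## dose to a single cell with the radionuclide on its surface
cfg <- scenario_config("Pd103_series", list(kind = "cell"),
                       "cell_surface", histories = 2e4, seed = 1)
tally <- run_scenario(cfg)
dose_table(tally)

## cluster with four unlabeled cells: heterogeneity in nuclear dose
het <- run_heterogeneous_cluster("Pd103_series", "nucleus",
                                 histories = 19 * 2000, seed = 1)
het[!het$labeled, ]
```
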