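Package: celldosim
Title: Monte Carlo Cellular Dosimetry for Auger- and Conversion-Electron Emitters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Event-by-event Monte Carlo transport of decay electrons in liquid
    water for cellular-scale dosimetry of radionuclide therapy candidates.
    Ships per-decay electron emission models for 103Pd, 103mRh, the combined
    103Pd(/103mRh) series, 177Lu and 161Tb; transports Auger electrons,
    conversion electrons and beta particles down to a 7.4 eV cutoff; and scores
    absorbed dose in spheres, a 14-micron single-cell model (nucleus, cytoplasm,
    10-nm membrane), a 19-cell cluster and a multi-cluster tumor model.
    Includes energy-density normalization (1 MeV per cubic micron), S-values,
    self/cross-dose splits, emission-category dose contributions,
    heterogeneous-labeling and dual-targeting scenarios, and closed-form
    decay/activity planning for a target nuclear dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
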