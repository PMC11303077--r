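# Minimal scheme constructor for degenerate/oracle cases: a single discrete
# line with a given energy, yield and category.
mono_scheme <- function(energy_keV, yield = 1, category = "CE",
                        name = "mono") {
  sch <- list(
    name = name,
    half_life_days = 1,
    lines = data.frame(energy_keV = energy_keV, yield = yield,
                       category = category, part = name),
    betas = NULL,
    electron_energy_per_decay = sum(energy_keV * yield),
    declared = list(electron_keV = sum(energy_keV * yield),
                    ae_keV = sum(energy_keV[category == "AE"] *
                                   yield[category == "AE"]),
                    ae_count = sum(yield[category == "AE"]),
                    ce_keV = NA_real_),
    parts = name,
    daughter = NULL
  )
  class(sch) <- "nuclide_scheme"
  sch
}

# batch standard error helper for a scalar dose
expect_close <- function(value, target, rel_tol, se = 0) {
  expect_lt(abs(value - target), max(rel_tol * abs(target), 3 * se))
}
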