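# Dose tallies: normalization arithmetic, bookkeeping identities and
# closed-form oracles.

test_that("energy-density normalization arithmetic", {
  rule <- normalization_rule()
  expect_equal(full_absorption_dose(rule), 160.218, tolerance = 1e-4)
  expect_equal(implied_decay_density(build_scheme("Pd103_series"), rule),
               1000 / 43.51)
  expect_equal(round(implied_decay_density(build_scheme("Pd103_series"))), 23)
  expect_equal(implied_decay_density(build_scheme("Lu177")), 6.76,
               tolerance = 1e-3)
  expect_equal(implied_decay_density(build_scheme("Tb161")), 4.94,
               tolerance = 1e-3)
})

test_that("fully absorbed degenerate source: S-value equals E/mass", {
  # 100 eV electrons have nanometer range; everything stays in the sphere
  sch <- mono_scheme(0.1)
  cfg <- scenario_config(sch, list(kind = "sphere", diameter_um = 2),
                         "uniform_sphere", 400, seed = 6,
                         normalization = normalization_rule("per_decay"),
                         settings = transport_settings(sampling = "expected"))
  t <- run_scenario(cfg)
  m <- sphere_model(2)$mass_kg
  expect_equal(s_value(t, "inside"), 0.1 * 1.602176634e-16 / m,
               tolerance = 0.01)
  expect_gt(retention_fraction(t), 0.99)
})

test_that("tallies conserve the released energy (inside + outside)", {
  cfg <- scenario_config("Pd103_series", list(kind = "sphere", diameter_um = 10),
                         "uniform_sphere", 300, seed = 3)
  t <- run_scenario(cfg)
  expect_equal(sum(t$energy_eV), sum(t$released_eV), tolerance = 1e-9)
  f <- retention_fraction(t)
  expect_gt(f, 0); expect_lt(f, 1)
})

test_that("sphere dose never exceeds the full-absorption bound", {
  cfg <- scenario_config("Pd103_series",
                         list(kind = "sphere", diameter_um = 500),
                         "uniform_sphere", 1200, seed = 5)
  t <- run_scenario(cfg)
  d <- dose(t, "inside")
  expect_lt(d$dose_Gy, full_absorption_dose() + 3 * d$stderr_Gy)
})

test_that("sphere-size monotonicity: S-values fall, normalized doses rise", {
  svals <- c(); ndose <- c()
  for (d in c(2, 10, 50)) {
    cfg <- scenario_config("Pd103_series", list(kind = "sphere", diameter_um = d),
                           "uniform_sphere", 1500, seed = 21,
                           normalization = normalization_rule("per_decay"))
    t <- run_scenario(cfg)
    svals <- c(svals, s_value(t, "inside"))
    # same histories re-normalized analytically to the energy-density rule
    ndose <- c(ndose, s_value(t, "inside") *
                 implied_decay_density(build_scheme("Pd103_series")) *
                 sphere_model(d)$volume_um3)
  }
  expect_true(all(diff(svals) < 0))   # S-value increases as spheres shrink
  expect_true(all(diff(ndose) > 0))   # normalized dose grows with size
})

test_that("cluster tally is the sum of single-labeled-cell tallies", {
  mask3 <- rep(FALSE, 19); mask3[c(1, 4, 9)] <- TRUE
  combined <- run_scenario(scenario_config(
    "Pd103_series", list(kind = "cluster", labeling_mask = mask3),
    "cell_surface", histories = 150, seed = 13))
  singles <- lapply(c(1, 4, 9), function(cell) {
    mask1 <- rep(FALSE, 19); mask1[cell] <- TRUE
    run_scenario(scenario_config(
      "Pd103_series", list(kind = "cluster", labeling_mask = mask1),
      "cell_surface", histories = 50, seed = 13))
  })
  sum_singles <- Reduce(`+`, lapply(singles, function(t)
    rowSums(t$energy_eV, dims = 4)))
  expect_equal(rowSums(combined$energy_eV, dims = 4), sum_singles,
               tolerance = 1e-12)
})

test_that("decay-series parts and emission categories sum to the total", {
  cfg <- scenario_config("Pd103_series", list(kind = "cell"), "cytoplasm",
                         500, seed = 4)
  t <- run_scenario(cfg)
  dt <- dose_table(t)
  expect_equal(dt$Pd103_Gy + dt$Rh103m_Gy, dt$dose_Gy, tolerance = 1e-12)
  frac <- dt$AE_fraction + dt$CE_fraction + dt$beta_fraction
  expect_equal(frac[dt$dose_Gy > 0], rep(1, sum(dt$dose_Gy > 0)),
               tolerance = 1e-12)
  # a CE-only scheme delivers everything as CE
  tce <- run_scenario(scenario_config(
    mono_scheme(30), list(kind = "cell"), "nucleus", 200, seed = 5))
  expect_equal(category_contribution(tce, "nucleus", "CE"), 1)
  expect_error(category_contribution(tce, "nucleus", "gamma"),
               "unknown category")
})

test_that("self/cross split: trivial and bookkeeping cases", {
  mask1 <- rep(FALSE, 19); mask1[1] <- TRUE
  t1 <- run_scenario(scenario_config(
    "Pd103_series", list(kind = "cluster", labeling_mask = mask1),
    "cell_surface", 100, seed = 2))
  sc <- self_cross_split(t1, 1)
  expect_equal(sc$self_fraction, 1)
  expect_equal(sc$cross_fraction, 0)

  tall <- run_scenario(scenario_config(
    "Pd103_series", list(kind = "cluster"), "cell_surface", 19 * 30, seed = 2))
  sc2 <- self_cross_split(tall, 1)
  expect_equal(sc2$self_fraction + sc2$cross_fraction, 1)
  expect_gt(sc2$cross_fraction, 0)
})

test_that("103mRh standalone rescale multiplies the Rh part by 1436.8/1244.6", {
  t <- run_scenario(scenario_config("Pd103_series", list(kind = "cell"),
                                    "cytoplasm", 300, seed = 9))
  rs <- rh_standalone_rescale(t)
  expect_equal(rs$rh_standalone_dose_Gy, rs$rh_dose_Gy * 1436.8 / 1244.6,
               tolerance = 1e-12)
  expect_equal(1436.8 / 1244.6, 1.154, tolerance = 1e-3)
  expect_true(all(rs$rh_standalone_dose_Gy[rs$rh_dose_Gy == 0] == 0))
  tmono <- run_scenario(scenario_config(mono_scheme(5), list(kind = "cell"),
                                        "nucleus", 50, seed = 1))
  expect_error(rh_standalone_rescale(tmono), "no Rh103m part")
})

test_that("per-decay tallies are required for S-values", {
  t <- run_scenario(scenario_config("Pd103", list(kind = "sphere", diameter_um = 5),
                                    "uniform_sphere", 100, seed = 1))
  expect_error(s_value(t, "inside"), "per-decay")
})

test_that("tally TSV export has the documented schema", {
  t <- run_scenario(scenario_config("Pd103_series", list(kind = "cell"),
                                    "nucleus", 100, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_tally_tsv(t, path)
  df <- read.delim(path)
  expect_true(all(c("geometry", "source_distribution", "nuclide", "cell",
                    "ring", "compartment", "dose_Gy", "stderr_Gy",
                    "self_fraction", "AE_fraction", "CE_fraction",
                    "beta_fraction") %in% names(df)))
  expect_equal(nrow(df), 3L)  # nucleus, cytoplasm, membrane of the one cell
})
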