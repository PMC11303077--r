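# Scenario configs, named experiments and activity planning.

test_that("scenario configs round-trip through YAML and JSON", {
  cfg <- scenario_config("Pd103_series",
                         list(kind = "cluster",
                              labeling_mask = default_heterogeneity_mask()),
                         "cell_surface", histories = 190, seed = 77,
                         normalization = normalization_rule("energy_density", 2))
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_scenario_config(cfg, path)
    back <- read_scenario_config(path)
    expect_equal(back$nuclide, "Pd103_series")
    expect_equal(back$distribution, cfg$distribution)
    expect_equal(back$histories, cfg$histories)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$normalization, cfg$normalization)
    expect_equal(.subset2(back$geometry, "labeling_mask"),
                 default_heterogeneity_mask())
  }
})

test_that("same config file and seed give identical output tables", {
  cfg <- scenario_config("Pd103", list(kind = "cell"), "nucleus", 60, seed = 5)
  path <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  t1 <- run_scenario(read_scenario_config(path))
  t2 <- run_scenario(read_scenario_config(path))
  expect_identical(dose_table(t1), dose_table(t2))
})

test_that("incompatible nuclide/geometry/distribution combinations fail early", {
  expect_error(scenario_config("Pd103", list(kind = "sphere", diameter_um = 10),
                               "cell_surface", 10), "incompatible")
  expect_error(scenario_config("Pd103", list(kind = "cluster"),
                               "uniform_sphere", 10), "sphere geometry")
  expect_error(scenario_config("Nope99", list(kind = "cell"), "nucleus", 10),
               "unknown nuclide")
})

test_that("decays needed for a 7.3 Gy nuclear dose match the closed form", {
  pd <- build_scheme("Pd103_series")
  # surface distribution, published nuclear dose 15.6 Gy per 1436.8 MeV
  expect_equal(decays_for_dose(7.3, 15.6, pd), 15400, tolerance = 0.005)
  expect_equal(decays_for_dose(7.3, 1.93, build_scheme("Lu177")), 36700,
               tolerance = 0.005)
  # identity: target equal to the tabulated dose needs one cell-equivalent
  expect_equal(decays_for_dose(15.6, 15.6, pd), 1436.8e3 / 43.51)
  expect_error(decays_for_dose(7.3, 0, pd), "positive")
})

test_that("initial activities for the 7.3 Gy reference point", {
  n_pd <- decays_for_dose(7.3, 15.6, build_scheme("Pd103_series"))
  expect_equal(initial_activity(n_pd, 16.991), 7.30e-3, tolerance = 0.005)
  n_lu <- decays_for_dose(7.3, 1.93, build_scheme("Lu177"))
  expect_equal(initial_activity(n_lu, 6.647), 44.4e-3, tolerance = 0.005)
  # inversion: N = T/ln2 seconds of decays is 1 Bq
  expect_equal(initial_activity(86400 / log(2), 1), 1)
  expect_error(initial_activity(100, -1), "positive")
  expect_error(initial_activity(0, 1), "not TRUE")
})

test_that("planning scales linearly in target dose, inversely in table dose", {
  pd <- build_scheme("Pd103_series")
  expect_equal(decays_for_dose(14.6, 15.6, pd),
               2 * decays_for_dose(7.3, 15.6, pd))
  expect_gt(decays_for_dose(7.3, 10, pd), decays_for_dose(7.3, 20, pd))
  expect_equal(initial_activity(2000, 10), 2 * initial_activity(1000, 10))
})

test_that("heterogeneous cluster with an all-labeled mask reproduces uniform", {
  out <- run_heterogeneous_cluster("Pd103_series", "nucleus",
                                   histories = 19 * 20,
                                   mask = rep(TRUE, 19), seed = 3)
  expect_equal(out$fraction_of_uniform, rep(1, 19))
  expect_error(run_heterogeneous_cluster("Pd103_series", "nucleus", 19,
                                         mask = rep(TRUE, 5)), "length 19")
})

test_that("unlabeled cells receive depressed doses under heterogeneity", {
  out <- run_heterogeneous_cluster("Pd103_series", "nucleus",
                                   histories = 19 * 150, seed = 4)
  expect_equal(sum(!out$labeled), 4L)
  expect_lt(max(out$fraction_of_uniform[!out$labeled]),
            min(out$fraction_of_uniform[out$labeled]))
  # intranuclear heterogeneity is severe: unlabeled nuclei get only cross-dose
  expect_lt(mean(out$fraction_of_uniform[!out$labeled]), 0.35)
})

test_that("dual targeting averages the two runs cell-by-cell", {
  mask_a <- default_heterogeneity_mask()
  mask_b <- rep(TRUE, 19); mask_b[c(3, 6, 11, 16)] <- FALSE  # cell 3 misses both
  out <- run_dual_targeting("Pd103_series", "nucleus", 19 * 100,
                            mask_a, mask_b, seed = 6)
  expect_equal(out$mean_dose_Gy, (out$dose_a_Gy + out$dose_b_Gy) / 2)
  expect_true(all(out$mean_dose_Gy >= pmin(out$dose_a_Gy, out$dose_b_Gy) - 1e-9))
  expect_true(all(out$mean_dose_Gy <= pmax(out$dose_a_Gy, out$dose_b_Gy) + 1e-9))
  # the doubly untargeted cell stays low in both runs
  others <- setdiff(which(!mask_a | !mask_b), 3)
  expect_lt(out$mean_dose_Gy[out$cell == 3],
            min(out$mean_dose_Gy[out$cell %in% setdiff(1:19, c(3, others))]))
  expect_warning(run_dual_targeting("Pd103", "nucleus", 19, mask_a, mask_a,
                                    seed = 1), "identical")
})

test_that("ratio tables use the reference denominator and validate grids", {
  ta <- run_scenario(scenario_config("Pd103_series", list(kind = "cell"),
                                     "nucleus", 150, seed = 8))
  tb <- run_scenario(scenario_config("Pd103_series", list(kind = "cell"),
                                     "nucleus", 150, seed = 8))
  rt <- ratio_table(list(Lu177 = ta, Pd = tb))
  expect_equal(rt$Pd_ratio, rep(1, nrow(rt)))
  tc <- run_scenario(scenario_config("Pd103_series", list(kind = "cell"),
                                     "cytoplasm", 150, seed = 8))
  expect_error(ratio_table(list(Lu177 = ta, Pd = tc)), "scenario grid")
})
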