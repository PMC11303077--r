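# Geometries: compartment partition, masses, cluster layouts, source
# sampling.

test_that("single-cell compartment classification and boundary conventions", {
  m <- cell_model()
  expect_equal(classify(m, c(4.9, 0, 0))$kind, "nucleus")
  expect_equal(classify(m, c(6.0, 0, 0))$kind, "cytoplasm")
  expect_equal(classify(m, c(6.995, 0, 0))$kind, "membrane")
  expect_equal(classify(m, c(7.1, 0, 0))$kind, "outside")
  # closed outer boundaries
  expect_equal(classify(m, c(5, 0, 0))$kind, "nucleus")
  expect_equal(classify(m, c(6.99, 0, 0))$kind, "cytoplasm")
  expect_equal(classify(m, c(7, 0, 0))$kind, "membrane")
  # partition: one compartment per point
  pts <- matrix(runif(300, -8, 8), ncol = 3)
  k <- classify(m, pts)$kind
  expect_true(all(k %in% c("nucleus", "cytoplasm", "membrane", "outside")))
})

test_that("compartment masses match the closed-form shell volumes", {
  m <- cell_model()
  expect_equal(compartment_mass(m, "cell"), 1.4368e-12, tolerance = 1e-3)
  expect_equal(compartment_mass(m, "nucleus"), 4 / 3 * pi * 125 * 1e-15,
               tolerance = 1e-12)
  shell <- 4 / 3 * pi * (7^3 - 6.99^3) * 1e-15
  expect_equal(compartment_mass(m, "membrane"), shell, tolerance = 1e-12)
  expect_equal(compartment_mass(m, "membrane"), 6.15e-15, tolerance = 2e-3)
  expect_equal(compartment_mass(m, "cell"),
               compartment_mass(m, "nucleus") +
                 compartment_mass(m, "cytoplasm") +
                 compartment_mass(m, "membrane"))
  # nucleus is 36% of the cell volume ((5/7)^3 = 0.3644 before rounding)
  expect_equal(compartment_mass(m, "nucleus") / compartment_mass(m, "cell"),
               0.36, tolerance = 0.015)
  expect_error(compartment_mass(m, "mitochondria"), "unknown compartment")
})

test_that("sphere model: volume, mass and supported diameters", {
  s <- sphere_model(10)
  expect_equal(s$volume_um3, pi * 1000 / 6)
  expect_equal(s$mass_kg, pi * 1000 / 6 * 1e-15)
  expect_error(sphere_model(0.5), "\\[1, 1000\\]")
  expect_error(sphere_model(2000), "\\[1, 1000\\]")
})

test_that("19-cell cluster: shell structure 1/6/12 and no overlap", {
  cl <- cluster_model()
  expect_equal(nrow(cl$centers), 19L)
  expect_equal(sum(cl$cells$ring == "central"), 1L)
  expect_equal(sum(cl$cells$ring == "first"), 6L)
  expect_equal(sum(cl$cells$ring == "second"), 12L)
  d <- sqrt(rowSums(cl$centers^2))
  expect_equal(d[cl$cells$ring == "first"], rep(14, 6))
  expect_equal(d[cl$cells$ring == "second"], rep(14 * sqrt(2), 12))
  dm <- as.matrix(dist(cl$centers)); diag(dm) <- Inf
  expect_gte(min(dm), 14)
  expect_error(cluster_model(spacing_um = 10), ">= 14")
  expect_error(cluster_model(labeling_mask = rep(TRUE, 5)), "length 19")
})

test_that("multi-cluster model: 7x19 cells, separation and overlap guards", {
  mc <- multicluster_model()
  expect_equal(nrow(mc$centers), 133L)
  expect_equal(sum(!mc$labeling_mask), 19L)
  dm <- as.matrix(dist(mc$centers)); diag(dm) <- Inf
  expect_gte(min(dm), 14 - 1e-9)
  # unlabeled central-cell nucleus at least 28 um from any labeled surface
  cen <- mc$cells[mc$cells$cluster == mc$unlabeled_cluster &
                    mc$cells$ring == "central", c("x_um", "y_um", "z_um")]
  lab <- mc$centers[mc$labeling_mask, ]
  gaps <- sqrt(colSums((t(lab) - as.numeric(cen))^2)) - 7 - 5
  expect_gte(min(gaps), 28)
  expect_error(multicluster_model(cluster_pitch_um = 50))
})

test_that("uniform-sphere source sampling matches closed-form moments", {
  s <- sphere_model(10)
  src <- sample_source(s, "uniform_sphere", 2e4, seed = 8)
  r3 <- (src$x_um^2 + src$y_um^2 + src$z_um^2)^1.5
  # E[r^3] = R^3/2 for uniform density in a ball; r^3/R^3 ~ U(0,1)
  se <- 125 / sqrt(12 * 2e4)
  expect_lt(abs(mean(r3) - 62.5), 4 * se)
  expect_lte(max(r3), 125)
})

test_that("cell-bound source distributions land in their compartments", {
  cl <- cluster_model()
  surf <- sample_source(cl, "cell_surface", 500, seed = 2)
  own <- cl$centers[surf$source_cell, ]
  r <- sqrt(rowSums((as.matrix(surf[, 1:3]) - own)^2))
  expect_true(all(abs(r - 7) < 1e-9))

  nuc <- sample_source(cl, "nucleus", 500, seed = 3)
  k <- classify(cl, as.matrix(nuc[, 1:3]))
  expect_true(all(k$kind == "nucleus"))
  expect_true(all(k$cell_index == nuc$source_cell))

  cyt <- sample_source(cl, "cytoplasm", 500, seed = 4)
  expect_true(all(classify(cl, as.matrix(cyt[, 1:3]))$kind == "cytoplasm"))

  # labeled cells only, equal weight
  mask <- rep(FALSE, 19); mask[c(1, 5)] <- TRUE
  s2 <- sample_source(cl, "nucleus", 400, seed = 5, labeling_mask = mask)
  expect_true(all(s2$source_cell %in% c(1, 5)))
  expect_error(sample_source(cl, "nucleus", 10, labeling_mask = rep(FALSE, 19)),
               "no labeled cell")
  expect_error(sample_source(cl, "uniform_sphere", 10), "incompatible")
  expect_error(sample_source(sphere_model(10), "nucleus", 10), "incompatible")
})

test_that("classification volumes converge to the analytic compartment volumes", {
  m <- cell_model()
  set.seed(31)
  n <- 2e5
  pts <- matrix(runif(3 * n, -7.05, 7.05), ncol = 3)
  k <- classify(m, pts)$kind
  vbox <- 14.1^3
  vol <- function(kind) sum(k == kind) / n * vbox
  expect_equal(vol("nucleus"), 4 / 3 * pi * 125, tolerance = 0.03)
  expect_equal(vol("cytoplasm"), 4 / 3 * pi * (6.99^3 - 125), tolerance = 0.03)
  # the 10-nm membrane is a tiny target; Poisson error dominates
  nmem <- sum(k == "membrane")
  lam <- 4 / 3 * pi * (7^3 - 6.99^3) / vbox * n
  expect_lt(abs(nmem - lam), 4 * sqrt(lam))
})

test_that("source positions are uniform within their compartment (chi-square)", {
  cl <- cell_model()
  nuc <- sample_source(cl, "nucleus", 5000, seed = 17)
  r <- sqrt(rowSums(as.matrix(nuc[, 1:3])^2))
  u <- (r / 5)^3                        # uniform in (0,1) for uniform density
  cosz <- nuc$z_um / r
  phi <- atan2(nuc$y_um, nuc$x_um)
  chisq <- function(x, lo, hi) {
    o <- table(cut(x, breaks = seq(lo, hi, length.out = 11)))
    e <- length(x) / 10
    sum((o - e)^2 / e)
  }
  crit <- qchisq(0.99, df = 9)
  expect_lt(chisq(u, 0, 1), crit)
  expect_lt(chisq(cosz, -1, 1), crit)
  expect_lt(chisq(phi, -pi, pi), crit)
})

test_that("geometry JSON export carries centers, rings and labels", {
  cl <- cluster_model(labeling_mask = default_heterogeneity_mask())
  js <- jsonlite::fromJSON(geometry_json(cl))
  expect_equal(js$kind, "cluster")
  expect_equal(nrow(js$cells), 19L)
  expect_equal(sum(!js$cells$labeled), 4L)
  expect_equal(js$nucleus_radius_um, 5)
})
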