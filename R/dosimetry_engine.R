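# Scenario runner and dose tallies.

#' Dose normalization rule
#'
#' Doses are reported either per decay (S-values) or for a fixed released
#' electron-energy density.  The energy-density mode follows the convention
#' of 1 MeV released per cubic micron, i.e. `1000 / E_decay` decays per cubic
#' micron for a nuclide releasing `E_decay` keV of electron energy per decay
#' (23.0 for 103Pd(/103mRh), 6.76 for 177Lu, 4.94 for 161Tb); full local
#' absorption of 1 MeV/um^3 corresponds to 160.2 Gy.  For labeled cells the
#' same density equals 1436.8 MeV released per 14-micron cell.
#'
#' @param mode `"energy_density"` or `"per_decay"`.
#' @param energy_density_MeV_um3 Released energy density (default 1).
#' @return A `normalization_rule` object.
#' @export
normalization_rule <- function(mode = c("energy_density", "per_decay"),
                               energy_density_MeV_um3 = 1) {
  mode <- match.arg(mode)
  stopifnot(energy_density_MeV_um3 > 0)
  out <- list(mode = mode, energy_density_MeV_um3 = energy_density_MeV_um3)
  class(out) <- "normalization_rule"
  out
}

#' Decay density implied by an energy-density normalization
#'
#' @param scheme A [build_scheme()] result.
#' @param rule A [normalization_rule()] (energy-density mode).
#' @return Decays per cubic micron.
#' @export
implied_decay_density <- function(scheme, rule = normalization_rule()) {
  stopifnot(rule$mode == "energy_density")
  rule$energy_density_MeV_um3 * 1000 / scheme$electron_energy_per_decay
}

#' Absorbed dose under complete local absorption
#'
#' Analytic bound: the dose in unit-density water if the released energy
#' density were absorbed where released (160.2 Gy at 1 MeV/um^3).
#'
#' @param rule A [normalization_rule()].
#' @return Dose in Gy.
#' @export
full_absorption_dose <- function(rule = normalization_rule()) {
  stopifnot(rule$mode == "energy_density")
  rule$energy_density_MeV_um3 * .FULL_ABSORPTION_GY
}

.as_scheme <- function(nuclide) {
  if (inherits(nuclide, "nuclide_scheme")) nuclide else build_scheme(nuclide)
}

.bins_map <- function(model) {
  if (inherits(model, "sphere_model")) {
    return(data.frame(bin = 0:1, cell = NA_integer_,
                      compartment = c("outside", "inside"),
                      ring = NA_character_))
  }
  nc <- nrow(model$centers)
  comp <- c("nucleus", "cytoplasm", "membrane")
  df <- data.frame(
    bin = c(0L, seq_len(3L * nc)),
    cell = c(NA_integer_, rep(seq_len(nc), each = 3)),
    compartment = c("outside", rep(comp, nc)),
    ring = c(NA_character_, rep(model$cells$ring, each = 3))
  )
  df
}

.bin_mass_kg <- function(tally) {
  bm <- tally$bins
  m <- numeric(nrow(bm))
  for (i in seq_len(nrow(bm))) {
    m[i] <- switch(bm$compartment[i],
      outside = NA_real_,
      inside = tally$model$mass_kg,
      compartment_mass(tally$model, bm$compartment[i]))
  }
  m
}

#' Run a simulation scenario
#'
#' Simulates decay histories of a nuclide in a geometry and accumulates
#' energy per target compartment, split by source cell, decay-series part
#' (e.g. 103Pd vs 103mRh) and emission category (AE / CE / beta).  Labeled
#' cells receive equal numbers of simulated decays and equal physical decay
#' numbers (equal released energy per labeled cell).  Statistical
#' uncertainties come from 10 independent history batches.
#'
#' @param config A [scenario_config()] object.
#' @return A `dose_tally` object; see [dose_table()], [s_value()],
#'   [self_cross_split()], [category_contribution()].
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  scheme <- .as_scheme(config$nuclide)
  model <- .build_geometry(config$geometry)
  settings <- config$settings
  norm <- config$normalization
  nbatch <- 10L

  sphere <- inherits(model, "sphere_model")
  if (sphere && config$distribution != "uniform_sphere")
    stop("sphere geometry requires distribution = 'uniform_sphere'",
         call. = FALSE)
  if (!sphere && !config$distribution %in% c("cell_surface", "cytoplasm", "nucleus"))
    stop("cell geometry requires a cell_surface/cytoplasm/nucleus ",
         "distribution", call. = FALSE)
  if (!is.null(config$labeling_mask) && !sphere)
    model$labeling_mask <- rep_len(config$labeling_mask, nrow(model$centers))

  cpp_scheme <- .scheme_to_cpp(scheme)
  bins <- .bins_map(model)
  nbins <- nrow(bins)

  if (sphere) {
    sources <- 0L
    n_hist <- as.integer(config$histories)
  } else {
    sources <- which(rep_len(model$labeling_mask, nrow(model$centers)))
    if (!length(sources)) stop("labeling mask has no labeled cell", call. = FALSE)
    h <- config$histories
    n_hist <- if (length(h) == 1L)
      rep(as.integer(ceiling(h / length(sources))), length(sources))
    else as.integer(rep_len(h, length(sources)))
  }

  energy <- array(0, dim = c(nbins, 3, 2, nbatch, length(sources)))
  released <- matrix(0, nbatch, length(sources))
  for (k in seq_along(sources)) {
    s <- sources[k]
    res <- cpp_run_histories(
      cpp_scheme,
      if (sphere) 1L else 2L,
      if (sphere) model$radius_um else 0,
      if (sphere) matrix(0, 0, 3) else model$centers,
      .dist_code(config$distribution),
      if (sphere) 0L else s - 1L,
      n_hist[k], nbatch, settings$cutoff_eV,
      as.integer(config$seed),
      as.integer(s + config$stream_offset),
      as.integer(settings$sampling == "expected"))
    energy[, , , , k] <- res$energy_eV
    released[, k] <- res$released_eV
  }

  # physical decays represented by each source's histories
  decays <- if (norm$mode == "per_decay") rep(NA_real_, length(sources))
  else if (sphere)
    rep(implied_decay_density(scheme, norm) * model$volume_um3,
        length(sources))
  else rep(.MEV_PER_LABELED_CELL * norm$energy_density_MeV_um3 * 1000 /
             scheme$electron_energy_per_decay, length(sources))

  out <- list(energy_eV = energy, bins = bins, sources = sources,
              n_hist = n_hist, decays_per_source = decays,
              scheme = scheme, model = model, normalization = norm,
              distribution = config$distribution, seed = config$seed,
              settings = settings, released_eV = released,
              parts = scheme$parts, n_batches = nbatch)
  class(out) <- "dose_tally"
  out
}

# per-source scale factors turning simulated energy (eV) into physical energy
.scale_per_source <- function(tally) {
  if (tally$normalization$mode == "per_decay") 1 / tally$n_hist
  else tally$decays_per_source / tally$n_hist
}

# energy (eV, physically scaled) summed over selected dimensions
# returns array [nbins, cat, part, batch] summed over sources, or by source
.scaled_energy <- function(tally, per_source = FALSE) {
  sc <- .scale_per_source(tally)
  e <- tally$energy_eV
  for (k in seq_along(sc)) e[, , , , k] <- e[, , , , k] * sc[k]
  if (per_source) e else rowSums(e, dims = 4)
}

#' Summarize a tally as a dose table
#'
#' One row per target cell and compartment: absorbed dose, batch standard
#' error, emission-category fractions, per-part doses and (for cell
#' geometries) the self-dose fraction.
#'
#' @param tally A [run_scenario()] result.
#' @return Data frame with columns `cell`, `ring`, `compartment`, `dose_Gy`,
#'   `stderr_Gy`, `self_fraction`, `AE_fraction`, `CE_fraction`,
#'   `beta_fraction` and one `<part>_Gy` column per decay-series part.
#'   Doses are per decay when the tally uses per-decay normalization.
#' @export
dose_table <- function(tally) {
  stopifnot(inherits(tally, "dose_tally"))
  es <- .scaled_energy(tally, per_source = TRUE) # [bins, cat, part, batch, src]
  bm <- tally$bins
  mass <- .bin_mass_kg(tally)
  keep <- !is.na(mass)
  nb <- tally$n_batches

  rows <- lapply(which(keep), function(b) {
    eb <- es[b, , , , , drop = FALSE]
    dim(eb) <- dim(es)[-1]
    tot <- sum(eb)
    bycat <- apply(eb, 1, sum)
    bypart <- apply(eb, 2, sum)
    bybatch <- apply(eb, 3, sum)
    dose <- tot * .EV_J / mass[b]
    se <- sd(bybatch * nb) / sqrt(nb) * .EV_J / mass[b]
    selff <- NA_real_
    if (!is.na(bm$cell[b]) && length(tally$sources) > 1) {
      bysrc <- apply(eb, 4, sum)
      own <- which(tally$sources == bm$cell[b])
      selff <- if (length(own) && tot > 0) bysrc[own] / tot else
        if (tot > 0) 0 else NA_real_
    } else if (!is.na(bm$cell[b]) && length(tally$sources) == 1) {
      selff <- if (tally$sources == bm$cell[b]) 1 else 0
    }
    parts <- setNames(as.list(bypart * .EV_J / mass[b]),
                      paste0(c(tally$parts, "part2")[1:2], "_Gy"))
    cbind(data.frame(cell = bm$cell[b], ring = bm$ring[b],
                     compartment = bm$compartment[b],
                     dose_Gy = dose, stderr_Gy = se, self_fraction = selff,
                     AE_fraction = if (tot > 0) bycat[1] / tot else NA_real_,
                     CE_fraction = if (tot > 0) bycat[2] / tot else NA_real_,
                     beta_fraction = if (tot > 0) bycat[3] / tot else NA_real_),
          as.data.frame(parts))
  })
  out <- do.call(rbind, rows)
  if (length(tally$parts) < 2) out$part2_Gy <- NULL
  rownames(out) <- NULL
  out
}

#' Absorbed dose for one target
#'
#' @param tally A [run_scenario()] result.
#' @param compartment Target compartment (`"inside"` for spheres,
#'   `"nucleus"`, `"cytoplasm"` or `"membrane"` for cells).
#' @param cell Target cell index (cell geometries).
#' @param part Optional part filter (e.g. `"Rh103m"`).
#' @param category Optional category filter (`"AE"`, `"CE"`, `"beta"`).
#' @return List with `dose_Gy` and `stderr_Gy`.
#' @export
dose <- function(tally, compartment, cell = 1L, part = NULL, category = NULL) {
  stopifnot(inherits(tally, "dose_tally"))
  bm <- tally$bins
  b <- if (inherits(tally$model, "sphere_model"))
    which(bm$compartment == compartment)
  else which(bm$compartment == compartment & bm$cell == cell)
  if (length(b) != 1L) stop("no such target", call. = FALSE)
  mass <- .bin_mass_kg(tally)[b]
  es <- .scaled_energy(tally) # [bins, cat, part, batch]
  ci <- if (is.null(category)) 1:3 else match(category, c("AE", "CE", "beta"))
  pi_ <- if (is.null(part)) seq_along(tally$parts) else match(part, tally$parts)
  if (anyNA(ci) || anyNA(pi_)) stop("unknown category or part", call. = FALSE)
  sel <- es[b, ci, pi_, , drop = FALSE]
  bybatch <- apply(sel, 4, sum)
  list(dose_Gy = sum(sel) * .EV_J / mass,
       stderr_Gy = sd(bybatch * tally$n_batches) / sqrt(tally$n_batches) *
         .EV_J / mass)
}

#' Electron S-value (mean absorbed dose per decay)
#'
#' @param tally A [run_scenario()] result with per-decay normalization.
#' @param compartment,cell Target (see [dose()]).
#' @return S-value in Gy per decay (Gy Bq^-1 s^-1).
#' @export
s_value <- function(tally, compartment = "inside", cell = 1L) {
  stopifnot(inherits(tally, "dose_tally"))
  if (tally$normalization$mode != "per_decay")
    stop("s_value requires a per-decay normalized tally", call. = FALSE)
  if (sum(tally$n_hist) < 1) stop("tally has no histories", call. = FALSE)
  dose(tally, compartment, cell)$dose_Gy
}

#' Self/cross dose split
#'
#' Fraction of a target's dose contributed by the target cell's own decays
#' (self-dose) versus decays in other cells (cross-dose).
#'
#' @param tally A cluster [run_scenario()] result.
#' @param target_cell Target cell index.
#' @param compartment Target compartment (default nucleus).
#' @return List with `self_fraction` and `cross_fraction` (summing to 1).
#' @export
self_cross_split <- function(tally, target_cell, compartment = "nucleus") {
  stopifnot(inherits(tally, "dose_tally"))
  bm <- tally$bins
  b <- which(bm$compartment == compartment & bm$cell == target_cell)
  if (length(b) != 1L) stop("no such target", call. = FALSE)
  es <- .scaled_energy(tally, per_source = TRUE)
  bysrc <- apply(es[b, , , , , drop = FALSE], 5, sum)
  tot <- sum(bysrc)
  own <- which(tally$sources == target_cell)
  selfe <- if (length(own)) bysrc[own] else 0
  if (length(tally$sources) == 1L && tally$sources == target_cell)
    return(list(self_fraction = 1, cross_fraction = 0))
  list(self_fraction = selfe / tot, cross_fraction = 1 - selfe / tot)
}

#' Emission-category contribution to a target dose
#'
#' @param tally A [run_scenario()] result.
#' @param compartment,cell Target (see [dose()]).
#' @param category `"AE"`, `"CE"` or `"beta"`.
#' @return Fraction of the target dose delivered by that emission category.
#' @export
category_contribution <- function(tally, compartment, category, cell = 1L) {
  if (!category %in% c("AE", "CE", "beta"))
    stop("unknown category '", category, "'; use AE, CE or beta",
         call. = FALSE)
  tot <- dose(tally, compartment, cell)$dose_Gy
  part <- dose(tally, compartment, cell, category = category)$dose_Gy
  part / tot
}

#' Rescale 103mRh-part doses to standalone 103mRh use
#'
#' Within the combined series normalization, 103mRh contributes 1244.6 MeV
#' of the 1436.8 MeV released per labeled cell.  If 103mRh were used on its
#' own at the same released energy per cell, its doses scale by
#' 1436.8 / 1244.6 = 1.154.
#'
#' @param tally A `Pd103_series` [run_scenario()] result.
#' @return Data frame `cell`, `compartment`, `rh_dose_Gy`,
#'   `rh_standalone_dose_Gy`.
#' @export
rh_standalone_rescale <- function(tally) {
  stopifnot(inherits(tally, "dose_tally"))
  if (!"Rh103m" %in% tally$parts)
    stop("tally has no Rh103m part; run the Pd103_series nuclide",
         call. = FALSE)
  factor <- 1436.8 / 1244.6
  bm <- tally$bins
  mass <- .bin_mass_kg(tally)
  keep <- which(!is.na(mass))
  es <- .scaled_energy(tally)
  pr <- match("Rh103m", tally$parts)
  rh <- vapply(keep, function(b) sum(es[b, , pr, ]) * .EV_J / mass[b], 0)
  data.frame(cell = bm$cell[keep], compartment = bm$compartment[keep],
             rh_dose_Gy = rh, rh_standalone_dose_Gy = rh * factor)
}

#' Fraction of released energy retained by the geometry
#'
#' @param tally A [run_scenario()] result.
#' @return Fraction in `[0, 1]` of all released electron energy deposited
#'   inside the geometry (everything except the `outside` bin).
#' @export
retention_fraction <- function(tally) {
  e <- rowSums(tally$energy_eV, dims = 1)
  sum(e[-1]) / sum(tally$released_eV)
}

#' @export
print.dose_tally <- function(x, ...) {
  cat("<dose_tally> ", x$scheme$name, ", ", x$model$kind, ", ",
      x$distribution, " source\n", sep = "")
  cat("  histories: ", sum(x$n_hist), " over ", length(x$sources),
      " source(s), seed ", x$seed, "\n", sep = "")
  cat("  normalization: ", x$normalization$mode,
      if (x$normalization$mode == "energy_density")
        sprintf(" (%.3g MeV/um^3)", x$normalization$energy_density_MeV_um3),
      "\n", sep = "")
  dt <- dose_table(x)
  print(utils::head(dt[order(-dt$dose_Gy), c("cell", "compartment", "dose_Gy",
                                             "stderr_Gy")], 8),
        row.names = FALSE)
  invisible(x)
}

#' Write a tally summary to TSV
#'
#' Stable machine-readable schema: one row per target with geometry,
#' source distribution, nuclide, ring, compartment, dose, batch standard
#' error, self-dose fraction, category fractions and per-part doses.
#'
#' @param tally A [run_scenario()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally_tsv <- function(tally, path) {
  dt <- dose_table(tally)
  dt <- cbind(data.frame(geometry = tally$model$kind,
                         source_distribution = tally$distribution,
                         nuclide = tally$scheme$name), dt)
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
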