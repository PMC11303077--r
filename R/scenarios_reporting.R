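# Declarative scenario configurations, named experiments and activity
# planning.

#' Scenario configuration
#'
#' Declarative description of one simulation: nuclide, geometry, source
#' distribution, labeling mask, normalization, number of histories and seed.
#' Configurations round-trip losslessly through YAML/JSON via
#' [write_scenario_config()] / [read_scenario_config()].
#'
#' @param nuclide Nuclide name (see [supported_nuclides()]) or a
#'   [build_scheme()] result.
#' @param geometry A geometry model object or a list spec:
#'   `list(kind = "sphere", diameter_um = )`, `list(kind = "cell")`,
#'   `list(kind = "cluster", spacing_um = , labeling_mask = )` or
#'   `list(kind = "multicluster", ...)`.
#' @param distribution `"uniform_sphere"`, `"cell_surface"`, `"cytoplasm"`
#'   or `"nucleus"`.
#' @param histories Total number of decay histories (split equally over
#'   labeled cells) or a per-labeled-cell vector.
#' @param seed Integer seed.
#' @param normalization A [normalization_rule()].
#' @param labeling_mask Optional logical mask overriding the geometry's.
#' @param settings A [transport_settings()].
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(nuclide, geometry, distribution, histories,
                            seed = 1L,
                            normalization = normalization_rule(),
                            labeling_mask = NULL,
                            settings = transport_settings()) {
  if (is.character(nuclide)) .as_scheme(nuclide) # validates the name early
  distribution <- match.arg(distribution,
                            c("uniform_sphere", "cell_surface", "cytoplasm",
                              "nucleus"))
  stopifnot(all(histories >= 1))
  out <- list(nuclide = nuclide, geometry = geometry,
              distribution = distribution, histories = histories,
              seed = as.integer(seed), normalization = normalization,
              labeling_mask = labeling_mask, settings = settings,
              stream_offset = 0L)
  class(out) <- "scenario_config"
  # geometry/distribution compatibility is validated before any compute
  .build_geometry(geometry)
  .check_compat(out)
  out
}

.check_compat <- function(config) {
  model <- .build_geometry(config$geometry)
  sphere <- inherits(model, "sphere_model")
  if (sphere && config$distribution != "uniform_sphere")
    stop("distribution '", config$distribution,
         "' is incompatible with a sphere geometry", call. = FALSE)
  if (!sphere && config$distribution == "uniform_sphere")
    stop("distribution 'uniform_sphere' requires a sphere geometry",
         call. = FALSE)
  invisible(TRUE)
}

.build_geometry <- function(g) {
  if (inherits(g, "geometry_model")) return(g)
  if (!is.list(g) || is.null(g$kind))
    stop("geometry must be a geometry model or a list with a 'kind'",
         call. = FALSE)
  switch(g$kind,
    sphere = sphere_model(g$diameter_um),
    cell = cell_model(),
    cluster = cluster_model(
      spacing_um = if (is.null(g$spacing_um)) 14 else g$spacing_um,
      labeling_mask = if (is.null(g$labeling_mask)) rep(TRUE, 19)
                      else as.logical(g$labeling_mask)),
    multicluster = multicluster_model(
      spacing_um = if (is.null(g$spacing_um)) 14 else g$spacing_um,
      cluster_pitch_um = if (is.null(g$cluster_pitch_um)) 60
                         else g$cluster_pitch_um,
      unlabeled_cluster = if (is.null(g$unlabeled_cluster)) 7L
                          else as.integer(g$unlabeled_cluster)),
    stop("unknown geometry kind '", g$kind, "'", call. = FALSE)
  )
}

# --- config serialization --------------------------------------------------

.config_to_list <- function(config) {
  g <- config$geometry
  gspec <- if (inherits(g, "geometry_model")) {
    switch(g$kind,
      sphere = list(kind = "sphere", diameter_um = g$diameter_um),
      cell = list(kind = "cell"),
      cluster = list(kind = "cluster", spacing_um = g$spacing_um,
                     labeling_mask = as.logical(g$labeling_mask)),
      multicluster = list(kind = "multicluster", spacing_um = g$spacing_um,
                          cluster_pitch_um = g$cluster_pitch_um,
                          unlabeled_cluster = g$unlabeled_cluster))
  } else g
  list(
    nuclide = if (is.character(config$nuclide)) config$nuclide
              else config$nuclide$name,
    geometry = gspec,
    distribution = config$distribution,
    histories = config$histories,
    seed = config$seed,
    normalization = list(mode = config$normalization$mode,
                         energy_density_MeV_um3 =
                           config$normalization$energy_density_MeV_um3),
    labeling_mask = config$labeling_mask,
    settings = list(cutoff_eV = config$settings$cutoff_eV,
                    sampling = config$settings$sampling)
  )
}

#' Write / read a scenario configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) by file extension.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  obj <- .config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  scenario_config(
    nuclide = obj$nuclide,
    geometry = obj$geometry,
    distribution = obj$distribution,
    histories = unlist(obj$histories),
    seed = obj$seed,
    normalization = normalization_rule(obj$normalization$mode,
                                       obj$normalization$energy_density_MeV_um3),
    labeling_mask = if (is.null(obj$labeling_mask)) NULL
                    else as.logical(unlist(obj$labeling_mask)),
    settings = transport_settings(obj$settings$cutoff_eV,
                                  obj$settings$sampling)
  )
}

# --- activity planning -----------------------------------------------------

#' Decays per cell needed to reach a target nuclear dose
#'
#' Closed-form planning: a labeled 14-micron cell releasing 1436.8 MeV
#' corresponds to `1436.8 MeV / E_decay` decays; scaling the tabulated dose
#' for that released energy to the target dose gives the required number of
#' decays per cell.
#'
#' @param target_dose_Gy Target dose (reference point 7.3 Gy to the
#'   nucleus).
#' @param dose_per_cell_energy_Gy Dose (Gy) delivered per 1436.8 MeV
#'   released per cell, from a tally or a published table.
#' @param scheme A [build_scheme()] result (or nuclide name).
#' @return Number of decays.
#' @export
decays_for_dose <- function(target_dose_Gy, dose_per_cell_energy_Gy, scheme) {
  if (!is.numeric(dose_per_cell_energy_Gy) || dose_per_cell_energy_Gy <= 0)
    stop("dose_per_cell_energy_Gy must be positive", call. = FALSE)
  stopifnot(target_dose_Gy > 0)
  scheme <- .as_scheme(scheme)
  (.MEV_PER_LABELED_CELL * 1000 / scheme$electron_energy_per_decay) *
    target_dose_Gy / dose_per_cell_energy_Gy
}

#' Initial activity for a given number of decays
#'
#' Assuming instant uptake and complete decay in situ, `N` total decays
#' correspond to an initial activity `A0 = N ln(2) / T_half`.
#'
#' @param decays Total number of decays.
#' @param half_life_days Physical half-life in days.
#' @return Initial activity in Bq.
#' @export
initial_activity <- function(decays, half_life_days) {
  if (!is.numeric(half_life_days) || half_life_days <= 0)
    stop("half_life_days must be positive", call. = FALSE)
  stopifnot(decays > 0)
  decays * log(2) / (half_life_days * 86400)
}

# --- named experiments -----------------------------------------------------

#' Heterogeneous-labeling cluster experiment
#'
#' Runs the 19-cell cluster with some cells unlabeled and, with the same
#' seed, the matching uniformly labeled cluster; reports each cell's dose
#' and its fraction of the uniform-targeting dose.
#'
#' @param nuclide Nuclide name or scheme.
#' @param distribution `"cell_surface"`, `"cytoplasm"` or `"nucleus"`.
#' @param histories Total histories for each run.
#' @param mask Logical length-19 labeling mask
#'   (default [default_heterogeneity_mask()]).
#' @param compartment Target compartment to report (default `"nucleus"`).
#' @param seed Integer seed.
#' @return Data frame `cell`, `ring`, `labeled`, `dose_Gy`,
#'   `uniform_dose_Gy`, `fraction_of_uniform`; the two tallies are attached
#'   as attributes `tally` and `uniform_tally`.
#' @export
run_heterogeneous_cluster <- function(nuclide = "Pd103_series", distribution,
                                      histories, mask = default_heterogeneity_mask(),
                                      compartment = "nucleus", seed = 1L) {
  if (length(mask) != 19L)
    stop("mask must have length 19", call. = FALSE)
  het <- run_scenario(scenario_config(
    nuclide, list(kind = "cluster", labeling_mask = mask),
    distribution, histories, seed = seed))
  uni <- run_scenario(scenario_config(
    nuclide, list(kind = "cluster"), distribution, histories, seed = seed))
  dh <- dose_table(het)
  du <- dose_table(uni)
  dh <- dh[dh$compartment == compartment, ]
  du <- du[du$compartment == compartment, ]
  out <- data.frame(cell = dh$cell, ring = dh$ring, labeled = mask[dh$cell],
                    dose_Gy = dh$dose_Gy, uniform_dose_Gy = du$dose_Gy,
                    fraction_of_uniform = dh$dose_Gy / du$dose_Gy)
  attr(out, "tally") <- het
  attr(out, "uniform_tally") <- uni
  out
}

#' Dual-targeting cluster experiment
#'
#' Two radiopharmaceuticals, each labeling a subset of the 19 cells, are
#' simulated independently and the per-cell doses averaged (each agent
#' contributes half the released energy).
#'
#' @param nuclide Nuclide name or scheme.
#' @param distribution Source distribution.
#' @param histories Total histories per run.
#' @param mask_a,mask_b Logical length-19 labeling masks.
#' @param compartment Target compartment to report.
#' @param seed Integer seed (the two runs use independent streams).
#' @return Data frame `cell`, `ring`, `dose_a_Gy`, `dose_b_Gy`,
#'   `mean_dose_Gy`; tallies attached as attributes `tally_a`, `tally_b`.
#' @export
run_dual_targeting <- function(nuclide = "Pd103_series", distribution,
                               histories, mask_a, mask_b,
                               compartment = "nucleus", seed = 1L) {
  stopifnot(length(mask_a) == 19L, length(mask_b) == 19L)
  if (identical(as.logical(mask_a), as.logical(mask_b)))
    warning("mask_a and mask_b are identical: degenerate dual-targeting")
  cfg_a <- scenario_config(nuclide, list(kind = "cluster", labeling_mask = mask_a),
                           distribution, histories, seed = seed)
  cfg_b <- scenario_config(nuclide, list(kind = "cluster", labeling_mask = mask_b),
                           distribution, histories, seed = seed)
  cfg_b$stream_offset <- 1000L
  ta <- run_scenario(cfg_a)
  tb <- run_scenario(cfg_b)
  da <- dose_table(ta); da <- da[da$compartment == compartment, ]
  db <- dose_table(tb); db <- db[db$compartment == compartment, ]
  out <- data.frame(cell = da$cell, ring = da$ring,
                    dose_a_Gy = da$dose_Gy, dose_b_Gy = db$dose_Gy,
                    mean_dose_Gy = (da$dose_Gy + db$dose_Gy) / 2)
  attr(out, "tally_a") <- ta
  attr(out, "tally_b") <- tb
  out
}

#' Nuclide-to-nuclide dose ratio table
#'
#' Element-wise dose ratios between tallies sharing the same geometry,
#' distribution and normalization, with 177Lu as the reference denominator.
#'
#' @param tallies Named list of [run_scenario()] results (names are nuclide
#'   labels).
#' @param reference Name of the reference tally (default `"Lu177"`).
#' @return Data frame `cell`, `compartment`, one `<name>_Gy` dose column per
#'   tally and one `<name>_ratio` column per non-reference tally, plus
#'   propagated `<name>_ratio_se`.
#' @export
ratio_table <- function(tallies, reference = "Lu177") {
  stopifnot(is.list(tallies), reference %in% names(tallies))
  base <- dose_table(tallies[[reference]])
  key <- paste(base$cell, base$compartment)
  for (nm in names(tallies)) {
    dt <- dose_table(tallies[[nm]])
    if (!identical(paste(dt$cell, dt$compartment), key) ||
        tallies[[nm]]$distribution != tallies[[reference]]$distribution)
      stop("tallies do not share the same scenario grid", call. = FALSE)
  }
  out <- base[, c("cell", "compartment")]
  for (nm in names(tallies)) {
    dt <- dose_table(tallies[[nm]])
    out[[paste0(nm, "_Gy")]] <- dt$dose_Gy
  }
  ref <- dose_table(tallies[[reference]])
  for (nm in setdiff(names(tallies), reference)) {
    dt <- dose_table(tallies[[nm]])
    r <- dt$dose_Gy / ref$dose_Gy
    out[[paste0(nm, "_ratio")]] <- r
    out[[paste0(nm, "_ratio_se")]] <- r *
      sqrt((dt$stderr_Gy / dt$dose_Gy)^2 + (ref$stderr_Gy / ref$dose_Gy)^2)
  }
  out
}
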