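# Scoring geometries: spheres, the 14-micron cell, the 19-cell cluster and
# the 7-cluster tumor model.
#
# Cell dimensions are fixed by the cell model: 14-micron cell diameter,
# 10-nm membrane (the outer shell of the cell sphere), 10-micron centered
# nucleus.  Compartment intervals are closed on their outer radius: the
# nucleus is r <= 5, the cytoplasm 5 < r <= 6.99, the membrane
# 6.99 < r <= 7 (micron).

.R_CELL <- 7.0
.R_MEM_IN <- 6.99
.R_NUC <- 5.0

#' Water sphere geometry
#'
#' @param diameter_um Sphere diameter, 1 to 1000 micron.
#' @return A `sphere_model` object with `diameter_um`, `radius_um`,
#'   `volume_um3` and `mass_kg` (unit-density water).
#' @export
sphere_model <- function(diameter_um) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1L ||
      diameter_um < 1 || diameter_um > 1000)
    stop("diameter_um must be in [1, 1000]", call. = FALSE)
  v <- pi * diameter_um^3 / 6
  out <- list(kind = "sphere", diameter_um = diameter_um,
              radius_um = diameter_um / 2, volume_um3 = v,
              mass_kg = v * 1e-15)
  class(out) <- c("sphere_model", "geometry_model")
  out
}

.cell_geometry_df <- function(centers, ring) {
  data.frame(cell = seq_len(nrow(centers)),
             x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
             ring = ring)
}

#' Single-cell geometry
#'
#' One 14-micron cell: 10-micron centered nucleus, 10-nm membrane.
#'
#' @param center Cell center, micron.
#' @return A `cell_model` object (a one-cell cluster).
#' @export
cell_model <- function(center = c(0, 0, 0)) {
  stopifnot(length(center) == 3L)
  centers <- matrix(as.numeric(center), 1, 3)
  out <- list(kind = "cell", centers = centers,
              cells = .cell_geometry_df(centers, "central"),
              labeling_mask = TRUE,
              cell_radius_um = .R_CELL, membrane_thickness_um = 0.01,
              nucleus_radius_um = .R_NUC)
  class(out) <- c("cell_model", "cell_geometry", "geometry_model")
  out
}

.cluster_centers <- function(spacing) {
  a <- spacing
  faces <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0),
                 c(0, 0, a), c(0, 0, -a))
  edges <- rbind(c(a, a, 0), c(a, -a, 0), c(-a, a, 0), c(-a, -a, 0),
                 c(a, 0, a), c(a, 0, -a), c(-a, 0, a), c(-a, 0, -a),
                 c(0, a, a), c(0, a, -a), c(0, -a, a), c(0, -a, -a))
  rbind(c(0, 0, 0), faces, edges)
}

#' 19-cell cluster geometry
#'
#' Three-dimensional cluster of 19 14-micron cells: a central cell (cell 1)
#' with its six immediate (touching) neighbors at one lattice spacing
#' (cells 2-7) and a second layer of twelve neighbors at `sqrt(2)` spacings
#' (cells 8-19) — the first and second coordination shells of a cubic
#' lattice.  Every second-layer cell touches four first-layer cells, so the
#' cluster is a compact 3-D cell packet.
#'
#' @param spacing_um Center-to-center spacing, at least 14 (touching cells).
#' @param labeling_mask Logical length-19 vector: which cells carry activity.
#' @return A `cluster_model` object: `centers`, `cells` (with ring labels),
#'   `labeling_mask`.
#' @export
cluster_model <- function(spacing_um = 14, labeling_mask = rep(TRUE, 19)) {
  if (!is.numeric(spacing_um) || spacing_um < 14)
    stop("spacing_um must be >= 14 (cells must not overlap)", call. = FALSE)
  if (length(labeling_mask) != 19L || !is.logical(labeling_mask))
    stop("labeling_mask must be a logical vector of length 19", call. = FALSE)
  centers <- .cluster_centers(spacing_um)
  d <- sqrt(rowSums(centers^2))
  ring <- ifelse(d < 1e-9, "central",
                 ifelse(abs(d - spacing_um) < 1e-6, "first", "second"))
  out <- list(kind = "cluster", centers = centers,
              cells = .cell_geometry_df(centers, ring),
              labeling_mask = labeling_mask, spacing_um = spacing_um,
              cell_radius_um = .R_CELL, membrane_thickness_um = 0.01,
              nucleus_radius_um = .R_NUC)
  class(out) <- c("cluster_model", "cell_geometry", "geometry_model")
  .check_overlap(out)
  out
}

#' Default heterogeneous labeling mask
#'
#' The shipped 15-of-19 mask used for the heterogeneity scenarios: cells
#' 3 (first ring) and 9, 13, 18 (second ring) unlabeled.  The identity of
#' the unlabeled cells is an assumption of this package, not a published
#' parameter.
#'
#' @return Logical vector of length 19.
#' @export
default_heterogeneity_mask <- function() {
  m <- rep(TRUE, 19)
  m[c(3, 9, 13, 18)] <- FALSE
  m
}

#' Multi-cluster tumor geometry
#'
#' Seven 19-cell clusters in a planar flower layout (one central, six
#' peripheral at `cluster_pitch_um`).  One cluster is unlabeled; all cells
#' of the remaining six are labeled.  The layout guarantees that the nucleus
#' of the unlabeled cluster's central cell is at least 28 micron away from
#' the nearest labeled cell surface.
#'
#' @param spacing_um Cell spacing within a cluster.
#' @param cluster_pitch_um Distance between adjacent cluster centers
#'   (default 60, giving a 28-micron nucleus-to-labeled-surface gap).
#' @param unlabeled_cluster Index (1-7) of the unlabeled cluster; default 7,
#'   a peripheral cluster.
#' @return A `multicluster_model` object; `cells` carries `cluster` and
#'   `ring` labels, `labeling_mask` is length 133.
#' @export
multicluster_model <- function(spacing_um = 14, cluster_pitch_um = 60,
                               unlabeled_cluster = 7L) {
  stopifnot(unlabeled_cluster %in% 1:7)
  base <- .cluster_centers(spacing_um)
  ang <- (0:5) * pi / 3
  ccent <- rbind(c(0, 0, 0), cbind(cluster_pitch_um * cos(ang),
                                   cluster_pitch_um * sin(ang), 0))
  centers <- NULL
  cluster_id <- integer(0)
  for (k in 1:7) {
    centers <- rbind(centers, sweep(base, 2, ccent[k, ], "+"))
    cluster_id <- c(cluster_id, rep(k, 19))
  }
  ring <- rep(c("central", rep("first", 6), rep("second", 12)), 7)
  mask <- cluster_id != unlabeled_cluster
  cells <- .cell_geometry_df(centers, ring)
  cells$cluster <- cluster_id
  out <- list(kind = "multicluster", centers = centers, cells = cells,
              labeling_mask = mask, spacing_um = spacing_um,
              cluster_pitch_um = cluster_pitch_um,
              unlabeled_cluster = as.integer(unlabeled_cluster),
              cluster_centers = ccent,
              cell_radius_um = .R_CELL, membrane_thickness_um = 0.01,
              nucleus_radius_um = .R_NUC)
  class(out) <- c("multicluster_model", "cell_geometry", "geometry_model")
  .check_overlap(out)
  # separation constraint: unlabeled central-cell nucleus to nearest labeled
  # cell surface
  gap <- .unlabeled_nucleus_gap(out)
  if (gap < 28 - 1e-6)
    stop(sprintf(paste0("multi-cluster layout violates the separation ",
                        "constraint: nucleus-to-labeled-surface gap %.2f um ",
                        "< 28 um"), gap), call. = FALSE)
  out
}

.unlabeled_nucleus_gap <- function(model) {
  cen <- model$cells[model$cells$cluster == model$unlabeled_cluster &
                       model$cells$ring == "central", c("x_um", "y_um", "z_um")]
  lab <- model$centers[model$labeling_mask, , drop = FALSE]
  d <- sqrt(colSums((t(lab) - as.numeric(cen))^2))
  min(d) - .R_CELL - .R_NUC
}

.check_overlap <- function(model) {
  cen <- model$centers
  if (nrow(cen) < 2) return(invisible(TRUE))
  dm <- as.matrix(dist(cen))
  diag(dm) <- Inf
  if (min(dm) < 2 * .R_CELL - 1e-9)
    stop("cell geometry has overlapping cells (min center distance ",
         format(min(dm)), " um)", call. = FALSE)
  invisible(TRUE)
}

#' Classify a point into a compartment
#'
#' Deterministic partition of space: every point belongs to exactly one of
#' nucleus, cytoplasm, membrane or outside (plus the owning cell index).
#' Boundary convention: intervals are closed on their outer radius, so
#' r = 7 belongs to the membrane and r = 5 to the nucleus.
#'
#' @param model A cell-type geometry (or [sphere_model()], where the
#'   compartments are `inside`/`outside`).
#' @param point Numeric length-3 position (micron), or an n-by-3 matrix.
#' @return Data frame with columns `kind` and `cell_index` (`NA` outside).
#' @export
classify <- function(model, point) {
  p <- if (is.matrix(point)) point else matrix(as.numeric(point), 1, 3)
  if (inherits(model, "sphere_model")) {
    r <- sqrt(rowSums(p^2))
    return(data.frame(kind = ifelse(r <= model$radius_um, "inside", "outside"),
                      cell_index = NA_integer_))
  }
  kind <- rep("outside", nrow(p))
  idx <- rep(NA_integer_, nrow(p))
  for (i in seq_len(nrow(model$centers))) {
    d2 <- (p[, 1] - model$centers[i, 1])^2 + (p[, 2] - model$centers[i, 2])^2 +
      (p[, 3] - model$centers[i, 3])^2
    inside <- d2 <= (.R_CELL + 1e-9)^2 & kind == "outside"
    if (!any(inside)) next
    r2 <- d2[inside]
    k <- ifelse(r2 <= .R_NUC^2, "nucleus",
                ifelse(r2 <= .R_MEM_IN^2, "cytoplasm", "membrane"))
    kind[inside] <- k
    idx[inside] <- i
  }
  data.frame(kind = kind, cell_index = idx)
}

#' Compartment mass
#'
#' Mass of a compartment at unit water density (1 g/cm^3).
#'
#' @param model A geometry model.
#' @param compartment For cell geometries one of `"cell"`, `"nucleus"`,
#'   `"cytoplasm"`, `"membrane"` (per cell); for spheres `"sphere"`.
#' @return Mass in kg.
#' @export
compartment_mass <- function(model, compartment) {
  vol_sphere <- function(r) 4 / 3 * pi * r^3
  v <- switch(compartment,
    sphere = {
      stopifnot(inherits(model, "sphere_model"))
      model$volume_um3
    },
    cell = vol_sphere(.R_CELL),
    nucleus = vol_sphere(.R_NUC),
    membrane = vol_sphere(.R_CELL) - vol_sphere(.R_MEM_IN),
    cytoplasm = vol_sphere(.R_MEM_IN) - vol_sphere(.R_NUC),
    stop("unknown compartment '", compartment, "'", call. = FALSE)
  )
  v * 1e-15
}

# distribution string -> engine code
.dist_code <- function(distribution) {
  match(distribution,
        c("point", "uniform_sphere", "cell_surface", "cytoplasm", "nucleus")) - 1L
}

#' Sample radionuclide source positions
#'
#' Draws decay sites for a given subcellular distribution: uniformly on the
#' outer membrane surface (r = 7 micron) of a labeled cell, uniformly in the
#' cytoplasmic shell, uniformly in the nucleus, or uniformly in a sphere.
#' Labeled cells are chosen with equal weight.
#'
#' @param model A geometry model.
#' @param distribution `"cell_surface"`, `"cytoplasm"`, `"nucleus"` or
#'   `"uniform_sphere"`.
#' @param n Number of positions.
#' @param seed Integer seed.
#' @param labeling_mask Optional logical mask overriding the model's.
#' @return Data frame `x_um`, `y_um`, `z_um`, `source_cell` (`NA` for
#'   spheres).
#' @export
sample_source <- function(model, distribution, n, seed = 1L,
                          labeling_mask = NULL) {
  if (inherits(model, "sphere_model")) {
    if (distribution != "uniform_sphere")
      stop("distribution '", distribution, "' is incompatible with a sphere; ",
           "use 'uniform_sphere'", call. = FALSE)
    res <- cpp_sample_source(1L, model$radius_um, matrix(0, 0, 3),
                             .dist_code("uniform_sphere"), 0L,
                             as.integer(n), as.integer(seed))
    p <- res$positions
    return(data.frame(x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
                      source_cell = NA_integer_))
  }
  if (!distribution %in% c("cell_surface", "cytoplasm", "nucleus"))
    stop("distribution '", distribution, "' is incompatible with a cell ",
         "geometry", call. = FALSE)
  mask <- if (is.null(labeling_mask)) model$labeling_mask else labeling_mask
  mask <- rep_len(mask, nrow(model$centers))
  if (!any(mask)) stop("labeling mask has no labeled cell", call. = FALSE)
  cells <- which(mask)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  src <- sample(cells, n, replace = TRUE)
  out <- matrix(0, n, 3)
  for (cell in unique(src)) {
    rows <- which(src == cell)
    res <- cpp_sample_source(2L, 0, model$centers,
                             .dist_code(distribution), cell - 1L,
                             length(rows), as.integer(seed) + cell)
    out[rows, ] <- res$positions
  }
  data.frame(x_um = out[, 1], y_um = out[, 2], z_um = out[, 3],
             source_cell = src)
}

#' Export a cell geometry as JSON
#'
#' @param model A geometry model.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
geometry_json <- function(model, path = NULL) {
  obj <- list(kind = model$kind,
              cell_radius_um = model$cell_radius_um,
              membrane_thickness_um = model$membrane_thickness_um,
              nucleus_radius_um = model$nucleus_radius_um,
              cells = cbind(model$cells,
                            labeled = rep_len(model$labeling_mask,
                                              nrow(model$cells))))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
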