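# Electron track transport in unbounded liquid water.

#' Transport settings
#'
#' Controls for the track-structure engine.  Energy transfers are scored
#' event by event until the electron energy falls below `cutoff_eV`
#' (default 7.4 eV); the residual energy is then deposited locally
#' (sub-excitation electrons are not diffused).  Above 10 keV the engine
#' switches to a condensed-history mode (restricted stopping power with
#' explicit delta-ray production above 1 keV); both modes share the same
#' screened-Rutherford elastic scattering.
#'
#' @param cutoff_eV Energy cutoff in eV, at least 7.4.
#' @param sampling `"poisson"` for analog per-decay emission statistics or
#'   `"expected"` for variance-free yield weighting.
#' @return A `transport_settings` list.
#' @export
transport_settings <- function(cutoff_eV = 7.4,
                               sampling = c("poisson", "expected")) {
  if (!is.numeric(cutoff_eV) || cutoff_eV < 7.4)
    stop("cutoff_eV must be >= 7.4 eV", call. = FALSE)
  out <- list(cutoff_eV = cutoff_eV, sampling = match.arg(sampling),
              tier_boundary_keV = 10, delta_threshold_keV = 1)
  class(out) <- "transport_settings"
  out
}

#' Transport a single electron
#'
#' Follows one electron (and all secondary electrons it liberates) through
#' unbounded liquid water, returning every local energy transfer.  The sum
#' of the deposited energies equals the initial kinetic energy exactly: the
#' medium is unbounded, so nothing escapes.
#'
#' @param energy_keV Initial kinetic energy (keV), above the cutoff.
#' @param origin Numeric length-3 start position, micron.
#' @param direction Numeric length-3 initial direction; normalized with a
#'   warning if not a unit vector.
#' @param settings A [transport_settings()] object.
#' @param seed Integer seed; identical seed and settings give an identical
#'   event list.
#' @return Data frame of deposition events (`x_um`, `y_um`, `z_um`,
#'   `edep_eV`) in track order, with attribute `edep_total_eV`.
#' @export
transport_electron <- function(energy_keV, origin = c(0, 0, 0),
                               direction = c(0, 0, 1),
                               settings = transport_settings(), seed = 1L) {
  if (!is.numeric(energy_keV) || length(energy_keV) != 1L || energy_keV <= 0)
    stop("energy_keV must be a single positive number", call. = FALSE)
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  if (abs(nrm - 1) > 1e-9) {
    warning("direction was not a unit vector; normalizing")
    direction <- direction / nrm
  }
  res <- cpp_transport_electron(energy_keV, as.numeric(origin),
                                as.numeric(direction),
                                settings$cutoff_eV, as.integer(seed), 0L)
  out <- data.frame(x_um = res$x_um, y_um = res$y_um, z_um = res$z_um,
                    edep_eV = res$edep_eV)
  attr(out, "edep_total_eV") <- res$edep_total_eV
  out
}

#' Write deposition events to TSV
#' @param events A [transport_electron()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collision stopping power of the transport model
#'
#' The engine's own electron stopping power in liquid water (keV/micron):
#' below 10 keV the sum over the discrete ionization and excitation channels,
#' above 10 keV the Bethe collision formula.  Used as the independent
#' continuous-slowing-down oracle for the stochastic transport.
#'
#' @param energy_keV Energies in keV.
#' @return Stopping power, keV/micron.
#' @export
stopping_power <- function(energy_keV) cpp_stopping_power(energy_keV)

#' Continuous-slowing-down (CSDA) range of the transport model
#'
#' Numerical integral of `1/S(E)` from the cutoff up to `energy_keV` over the
#' model's own stopping power.
#'
#' @param energy_keV Energies in keV.
#' @return CSDA range, micron.
#' @export
csda_range <- function(energy_keV) cpp_csda_range(energy_keV)

#' Radial energy-deposition profile of a point source
#'
#' Simulates decays of `scheme` at the origin of unbounded water and bins all
#' energy transfers into concentric spherical shells.
#'
#' @param scheme A [build_scheme()] result.
#' @param n_histories Number of decays.
#' @param shell_width_nm Shell thickness, nm (default 1 nm).
#' @param r_max_um Outer radius of the binned region; deposits beyond it are
#'   kept in an overflow bin so fractions still sum to one.
#' @param settings A [transport_settings()] object.
#' @param seed Integer seed.
#' @return A `radial_profile` object: data frame `shells` with `r_inner_um`,
#'   `r_outer_um`, `energy_eV`, `fraction`, plus `overflow_fraction`,
#'   `released_eV`, `n_histories`.
#' @export
radial_profile <- function(scheme, n_histories, shell_width_nm = 1,
                           r_max_um = 45, settings = transport_settings(),
                           seed = 1L) {
  stopifnot(inherits(scheme, "nuclide_scheme"), n_histories >= 1)
  shell_um <- shell_width_nm * 1e-3
  n_shells <- as.integer(ceiling(r_max_um / shell_um))
  res <- cpp_radial_profile(.scheme_to_cpp(scheme), as.integer(n_histories),
                            shell_um, n_shells, settings$cutoff_eV,
                            as.integer(seed),
                            as.integer(settings$sampling == "expected"))
  e <- res$energy_eV
  total <- sum(e)
  shells <- data.frame(
    r_inner_um = (seq_len(n_shells) - 1) * shell_um,
    r_outer_um = seq_len(n_shells) * shell_um,
    energy_eV = e[seq_len(n_shells)]
  )
  shells$fraction <- shells$energy_eV / total
  out <- list(shells = shells,
              overflow_energy_eV = e[n_shells + 1],
              overflow_fraction = e[n_shells + 1] / total,
              released_eV = res$released_eV,
              n_histories = n_histories,
              scheme = scheme$name)
  class(out) <- "radial_profile"
  out
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("<radial_profile> ", x$scheme, ", ", x$n_histories, " decays\n", sep = "")
  cat(sprintf("  deposited %.4g eV (%.4g eV released per decay)\n",
              sum(x$shells$energy_eV) + x$overflow_energy_eV,
              x$released_eV / x$n_histories))
  for (q in c(0.5, 0.9, 0.99))
    cat(sprintf("  R%d = %.3g um\n", round(100 * q), r_quantile(x, q)))
  invisible(x)
}

#' Radius enclosing a fraction of the deposited energy
#'
#' Smallest shell outer radius whose enclosed cumulative energy reaches at
#' least fraction `q` of the total deposited energy (R99 for `q = 0.99`).
#'
#' @param profile A [radial_profile()] result.
#' @param q Fraction in (0, 1).
#' @return Radius in micron (`NA` if the quantile lies beyond the binned
#'   region).
#' @export
r_quantile <- function(profile, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must be a single fraction in (0, 1)", call. = FALSE)
  total <- sum(profile$shells$energy_eV) + profile$overflow_energy_eV
  cum <- cumsum(profile$shells$energy_eV) / total
  i <- which(cum >= q)[1]
  if (is.na(i)) return(NA_real_)
  profile$shells$r_outer_um[i]
}
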