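#' Convert correlation amplitudes to concentrations and bound fractions
#'
#' Dual-colour amplitude relations: with effective volume `V` (in litres)
#' and Avogadro's number `N_A`,
#' total concentrations are `c_g = 1/(V N_A G0_green)` and
#' `c_r = 1/(V N_A G0_red)`; the complex concentration is
#' `c_gr = G0_cross / (V N_A G0_green G0_red)`; bound fractions are
#' `f_bound_green = G0_cross / G0_red` and `f_bound_red = G0_cross /
#' G0_green`. Free concentrations are totals minus complex. Fractions
#' outside `[0, 1]` (possible with noisy amplitudes) are clipped and the
#' measurement is flagged.
#'
#' @param g0_green,g0_red Zero-lag autocorrelation amplitudes (> 0).
#' @param g0_cross Zero-lag cross-correlation amplitude (>= 0; negative
#'   noisy estimates are clipped to 0 with a flag).
#' @param volume A [confocal_volume()].
#' @param meta Optional metadata list (cell id, compartment, cpm_kHz, ...).
#' @param tol Relative tolerance above which `c_complex > min(totals)` is
#'   flagged as inconsistent (amplitudes are then clipped to the limiting
#'   total).
#'
#' @return An object of class `cell_measurement`: amplitudes, `c_g_total`,
#'   `c_r_total`, `c_complex`, `c_g_free`, `c_r_free` (nM),
#'   `f_bound_green`, `f_bound_red`, `flags`, `qc_pass` (set by
#'   [qc_cell()], `NA` until then), `meta`.
#' @examples
#' vol <- confocal_volume(v_eff = 1, s = 5)
#' m <- amplitudes_to_concentrations(1, 1, 0, vol)
#' m$c_g_total  # ~1.661 nM: one molecule per femtolitre
#' @export
amplitudes_to_concentrations <- function(g0_green, g0_red, g0_cross, volume,
                                         meta = list(), tol = 1e-6) {
  stopifnot(inherits(volume, "confocal_volume"))
  flags <- character(0)
  if (!is.finite(g0_green) || !is.finite(g0_red) ||
      g0_green <= 0 || g0_red <= 0) {
    stop("amplitudes_to_concentrations: autocorrelation amplitudes must be > 0")
  }
  if (!is.finite(g0_cross)) stop("amplitudes_to_concentrations: g0_cross must be finite")
  if (g0_cross < 0) {
    flags <- c(flags, "clipped")
    g0_cross <- 0
  }
  unit <- .nM_per_molecule(volume$v_eff)  # nM per (1/G0) molecule
  c_g_total <- unit / g0_green
  c_r_total <- unit / g0_red
  c_complex <- unit * g0_cross / (g0_green * g0_red)
  lim <- min(c_g_total, c_r_total)
  if (c_complex > lim * (1 + tol)) {
    flags <- c(flags, "inconsistent")
  }
  c_complex <- min(c_complex, lim)
  f_bg <- g0_cross / g0_red
  f_br <- g0_cross / g0_green
  if (f_bg > 1 || f_br > 1) flags <- c(flags, "clipped")
  f_bg <- min(max(f_bg, 0), 1)
  f_br <- min(max(f_br, 0), 1)
  structure(
    list(g0_green = g0_green, g0_red = g0_red, g0_cross = g0_cross,
         c_g_total = c_g_total, c_r_total = c_r_total,
         c_complex = c_complex,
         c_g_free = c_g_total - c_complex, c_r_free = c_r_total - c_complex,
         f_bound_green = f_bg, f_bound_red = f_br,
         flags = unique(flags), qc_pass = NA, meta = meta),
    class = "cell_measurement"
  )
}

#' @export
print.cell_measurement <- function(x, ...) {
  cat(sprintf("cell measurement: c_g %.3g nM, c_r %.3g nM, complex %.3g nM\n",
              x$c_g_total, x$c_r_total, x$c_complex))
  cat(sprintf("  bound fractions: green %.3f, red %.3f; qc_pass = %s\n",
              x$f_bound_green, x$f_bound_red, x$qc_pass))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Quality-control a single-cell FCCS measurement
#'
#' Cells enter the binding-isotherm fit only if their counts per molecule
#' (molecular brightness) reach the threshold, all autocorrelation
#' amplitudes are positive, and the curve fits converged. Reason codes for
#' failures are recorded on the measurement.
#'
#' @param measurement A [amplitudes_to_concentrations()] result.
#' @param fits Optional list of `fccs_fit` objects for the cell's curves;
#'   any non-converged fit fails QC.
#' @param cpm_min_kHz Minimum counts per molecule (kHz); the `cpm_kHz`
#'   metadata entry (scalar or per-channel vector) is checked when present.
#' @return The measurement with `qc_pass` set and reason codes appended to
#'   `flags`.
#' @export
qc_cell <- function(measurement, fits = NULL, cpm_min_kHz = 0.5) {
  stopifnot(inherits(measurement, "cell_measurement"))
  reasons <- character(0)
  if (!is.finite(measurement$g0_green) || measurement$g0_green <= 0 ||
      !is.finite(measurement$g0_red) || measurement$g0_red <= 0 ||
      measurement$g0_cross < 0) {
    reasons <- c(reasons, "amplitude")
  }
  cpm <- measurement$meta$cpm_kHz
  if (!is.null(cpm) && any(cpm < cpm_min_kHz)) reasons <- c(reasons, "cpm")
  if (!is.null(fits)) {
    if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
      reasons <- c(reasons, "fit")
    }
  }
  measurement$qc_pass <- length(reasons) == 0L
  measurement$flags <- unique(c(measurement$flags, reasons))
  measurement
}
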