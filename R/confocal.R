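#' Avogadro constant (1/mol), CODATA exact value.
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23

# molecules in v_eff (fL) at concentration c (nM):
#   N = c * 1e-9 mol/L * N_A * v_eff * 1e-15 L
.molecules_per_veff <- function(c_nM, v_eff_fL) {
  c_nM * 1e-9 * .N_AVOGADRO * v_eff_fL * 1e-15
}

.nM_per_molecule <- function(v_eff_fL) {
  1 / (1e-9 * .N_AVOGADRO * v_eff_fL * 1e-15)
}

#' Define a calibrated confocal detection volume
#'
#' The effective confocal volume converts correlation amplitudes to molar
#' concentrations: a correlation amplitude `G(0) = 1/N` corresponds to `N`
#' molecules in `v_eff`. The structure parameter `s` is the axial-to-lateral
#' ratio of the 3D Gaussian detection profile and enters the diffusion term
#' of the correlation models.
#'
#' @param v_eff Effective volume in femtolitres (must be > 0). For a 3D
#'   Gaussian profile `v_eff = pi^(3/2) * w0^3 * s`.
#' @param s Structure parameter (axial/lateral 1/e^2 radius ratio), > 1.
#' @param w0 Optional lateral 1/e^2 beam-waist radius in micrometres. If
#'   supplied and `v_eff` is missing, `v_eff` is derived from `w0` and `s`.
#'
#' @return An object of class `confocal_volume` with fields `v_eff` (fL),
#'   `s`, `w0` (um or `NA`).
#' @examples
#' vol <- confocal_volume(v_eff = 0.25, s = 5)
#' @export
confocal_volume <- function(v_eff = NULL, s = 5, w0 = NA_real_) {
  if (is.null(v_eff)) {
    if (!is.finite(w0) || w0 <= 0) {
      stop("confocal_volume: supply v_eff or a positive w0")
    }
    v_eff <- pi^(3 / 2) * w0^3 * s  # um^3 == fL
  }
  if (!is.finite(v_eff) || v_eff <= 0) stop("confocal_volume: v_eff must be > 0")
  if (!is.finite(s) || s <= 1) stop("confocal_volume: structure parameter s must be > 1")
  structure(list(v_eff = v_eff, s = s, w0 = w0), class = "confocal_volume")
}

#' @export
print.confocal_volume <- function(x, ...) {
  cat(sprintf("confocal volume: v_eff = %.4g fL, s = %.3g, w0 = %s um\n",
              x$v_eff, x$s,
              if (is.finite(x$w0)) sprintf("%.3g", x$w0) else "uncalibrated"))
  invisible(x)
}
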