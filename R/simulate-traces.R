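#' Simulate photon-count traces by Brownian dynamics
#'
#' Desk-scale physics oracle for the correlator and the analytic diffusion
#' models: point particles (free green, free red, and double-labelled
#' complex) diffuse in a periodic cubic box centred on a 3D-Gaussian
#' detection volume. Each particle contributes a detection weight
#' `exp(-2 (x^2 + y^2) / w0^2 - 2 z^2 / (s w0)^2)` (coordinates relative to
#' the focus); free species emit in their own channel, complexes in both.
#' Photon counts per time bin are Poisson with mean `brightness` times the
#' summed weights.
#'
#' Particle numbers are derived from the equilibrium concentrations and the
#' box volume. This routine is intentionally small-scale (at most 200
#' particles and 2^20 steps); it exists to validate the estimators, not to
#' emulate an instrument.
#'
#' @param state An [solve_equilibrium()] result (nM concentrations).
#' @param volume A [confocal_volume()] with a finite beam waist `w0`.
#' @param diffusion_coeffs Named numeric vector or list with entries
#'   `green`, `red`, `complex`: diffusion coefficients in um^2/s.
#' @param dt Bin width in seconds (> 0).
#' @param n_steps Number of time bins (<= 2^20).
#' @param seed Integer seed.
#' @param box_factor Box side in units of `w0` (>= 10).
#' @param brightness Mean photons per particle per bin at the focus.
#' @return List with integer traces `green` and `red`, the bin width `dt`,
#'   and the realised particle counts `n_particles`.
#' @export
simulate_photon_traces <- function(state, volume, diffusion_coeffs, dt,
                                   n_steps, seed = 1L, box_factor = 12,
                                   brightness = 2) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(volume, "confocal_volume"))
  if (!is.finite(dt) || dt <= 0) stop("simulate_photon_traces: dt must be > 0")
  if (box_factor < 10) {
    stop("simulate_photon_traces: box must be at least 10 beam waists wide")
  }
  if (!is.finite(volume$w0) || volume$w0 <= 0) {
    stop("simulate_photon_traces: volume must carry a beam waist w0")
  }
  if (n_steps > 2^20) stop("simulate_photon_traces: n_steps capped at 2^20")
  dc <- diffusion_coeffs
  for (nm in c("green", "red", "complex")) {
    if (is.null(dc[[nm]]) || dc[[nm]] < 0) {
      stop("simulate_photon_traces: diffusion_coeffs needs non-negative green/red/complex")
    }
  }
  set.seed(seed)
  w0 <- volume$w0
  # box sides in units of the waist of each axis: the axial 1/e^2 radius is
  # s*w0, so the z side must scale with it or wrap-around truncates the
  # detection profile and biases apparent diffusion times
  L <- box_factor * w0
  Lz <- box_factor * volume$s * w0
  v_box_fL <- L * L * Lz  # um^3 == fL
  n_of <- function(c_nM) round(.molecules_per_veff(c_nM, v_box_fL))
  counts <- c(green = n_of(state$c_g_free), red = n_of(state$c_r_free),
              complex = n_of(state$c_complex))
  if (sum(counts) > 200) {
    stop("simulate_photon_traces: more than 200 particles; reduce concentrations or box")
  }

  s <- volume$s
  half <- L / 2
  half_z <- Lz / 2
  rate_g <- numeric(n_steps)
  rate_r <- numeric(n_steps)
  for (sp in names(counts)) {
    n_sp <- counts[[sp]]
    if (n_sp == 0) next
    sd_step <- sqrt(2 * dc[[sp]] * dt)
    for (p in seq_len(n_sp)) {
      x <- (stats::runif(1, 0, L) + cumsum(c(0, stats::rnorm(n_steps - 1, 0, sd_step)))) %% L
      y <- (stats::runif(1, 0, L) + cumsum(c(0, stats::rnorm(n_steps - 1, 0, sd_step)))) %% L
      z <- (stats::runif(1, 0, Lz) + cumsum(c(0, stats::rnorm(n_steps - 1, 0, sd_step)))) %% Lz
      wgt <- exp(-2 * ((x - half)^2 + (y - half)^2) / w0^2 -
                   2 * (z - half_z)^2 / (s * w0)^2)
      if (sp != "red") rate_g <- rate_g + wgt
      if (sp != "green") rate_r <- rate_r + wgt
    }
  }
  list(green = stats::rpois(n_steps, brightness * rate_g),
       red = stats::rpois(n_steps, brightness * rate_r),
       dt = dt, n_particles = counts, box_um = c(L, L, Lz))
}
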