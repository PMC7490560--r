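#' Parameters of the two-component diffusion correlation model
#'
#' Container for the parameters of the analytic FCS correlation models:
#' mean particle number `n_particles` in the effective volume, two diffusing
#' components with fractions `f_fast + f_slow = 1` and diffusion times
#' `tau_d_fast <= tau_d_slow` (seconds), an optional triplet (dark-state)
#' term with fraction `triplet_fraction` in `[0, 1)` and relaxation time
#' `tau_triplet`, and a baseline `offset`.
#'
#' @param n_particles Mean number of molecules in the effective volume (> 0).
#' @param f_fast Fraction of the fast component in `[0, 1]`; `f_slow` is
#'   `1 - f_fast`.
#' @param tau_d_fast,tau_d_slow Diffusion times in seconds (> 0,
#'   `tau_d_fast <= tau_d_slow`).
#' @param triplet_fraction Triplet fraction `T` in `[0, 1)`.
#' @param tau_triplet Triplet relaxation time in seconds (> 0).
#' @param offset Additive baseline (the long-lag limit of the model).
#' @param covariance Optional covariance matrix of the estimates (filled by
#'   [fit_correlation_curve()]).
#'
#' @return An object of class `diffusion_params`.
#' @examples
#' p <- diffusion_params(n_particles = 10, f_fast = 1, tau_d_fast = 1e-3)
#' @export
diffusion_params <- function(n_particles, f_fast = 1, tau_d_fast,
                             tau_d_slow = tau_d_fast, triplet_fraction = 0,
                             tau_triplet = 5e-6, offset = 0,
                             covariance = NULL) {
  if (!is.finite(n_particles) || n_particles <= 0) {
    stop("diffusion_params: n_particles must be > 0")
  }
  if (!is.finite(f_fast) || f_fast < 0 || f_fast > 1) {
    stop("diffusion_params: f_fast must lie in [0, 1]")
  }
  if (!is.finite(tau_d_fast) || tau_d_fast <= 0 ||
      !is.finite(tau_d_slow) || tau_d_slow <= 0) {
    stop("diffusion_params: diffusion times must be > 0")
  }
  if (tau_d_fast > tau_d_slow) {
    stop("diffusion_params: tau_d_fast must not exceed tau_d_slow")
  }
  if (!is.finite(triplet_fraction) || triplet_fraction < 0 ||
      triplet_fraction >= 1) {
    stop("diffusion_params: triplet_fraction must lie in [0, 1)")
  }
  if (!is.finite(tau_triplet) || tau_triplet <= 0) {
    stop("diffusion_params: tau_triplet must be > 0")
  }
  structure(
    list(n_particles = n_particles, f_fast = f_fast, f_slow = 1 - f_fast,
         tau_d_fast = tau_d_fast, tau_d_slow = tau_d_slow,
         triplet_fraction = triplet_fraction, tau_triplet = tau_triplet,
         offset = offset, covariance = covariance),
    class = "diffusion_params"
  )
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("two-component diffusion model parameters\n")
  cat(sprintf("  N = %.4g, f_fast = %.3f, tau_D = %.3g / %.3g s\n",
              x$n_particles, x$f_fast, x$tau_d_fast, x$tau_d_slow))
  cat(sprintf("  triplet T = %.3f (tau_T = %.3g s), offset = %.3g\n",
              x$triplet_fraction, x$tau_triplet, x$offset))
  invisible(x)
}

# diffusion factor sum_i f_i (1 + tau/tau_Di)^-1 (1 + tau/(s^2 tau_Di))^-1/2
.diffusion_term <- function(lags, f_fast, tau_fast, tau_slow, s) {
  s2 <- s * s
  f_fast / ((1 + lags / tau_fast) * sqrt(1 + lags / (s2 * tau_fast))) +
    (1 - f_fast) / ((1 + lags / tau_slow) * sqrt(1 + lags / (s2 * tau_slow)))
}

#' Evaluate the autocorrelation model
#'
#' Two-component 3D-diffusion autocorrelation with triplet correction:
#' \deqn{G(\tau) = \mathrm{offset} + \left[1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right]
#'   \frac{1}{N} \sum_i f_i \left(1+\frac{\tau}{\tau_{D,i}}\right)^{-1}
#'   \left(1+\frac{\tau}{s^2\tau_{D,i}}\right)^{-1/2}.}
#' At `tau = 0` (with `T = 0`, `offset = 0`) the amplitude is `1/N`.
#'
#' @param lags Lag times in seconds (non-negative).
#' @param params A [diffusion_params()] object.
#' @param volume A [confocal_volume()] object (supplies the structure
#'   parameter `s`).
#' @return Numeric vector of correlation amplitudes, one per lag.
#' @examples
#' vol <- confocal_volume(0.25, s = 5)
#' p <- diffusion_params(10, 1, 1e-3)
#' eval_autocorr_model(0, p, vol)  # 1/N = 0.1
#' @export
eval_autocorr_model <- function(lags, params, volume) {
  stopifnot(inherits(params, "diffusion_params"),
            inherits(volume, "confocal_volume"))
  if (any(!is.finite(lags)) || any(lags < 0)) {
    stop("eval_autocorr_model: lags must be finite and non-negative")
  }
  T <- params$triplet_fraction
  trip <- if (T > 0) 1 + (T / (1 - T)) * exp(-lags / params$tau_triplet) else 1
  params$offset + trip * .diffusion_term(
    lags, params$f_fast, params$tau_d_fast, params$tau_d_slow, volume$s
  ) / params$n_particles
}

#' Evaluate the cross-correlation model
#'
#' Identical to [eval_autocorr_model()] with the triplet term forced to
#' zero: dark-state blinking is uncorrelated between spectrally distinct
#' fluorophores, so cross-correlation curves are fitted without it.
#'
#' @inheritParams eval_autocorr_model
#' @return Numeric vector of correlation amplitudes, one per lag.
#' @export
eval_crosscorr_model <- function(lags, params, volume) {
  stopifnot(inherits(params, "diffusion_params"))
  params$triplet_fraction <- 0
  eval_autocorr_model(lags, params, volume)
}
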