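#' Configuration for simulated single-cell FCCS populations
#'
#' Describes the study conditions of a simulated FCCS experiment:
#' cell-to-cell expression heterogeneity (log-normal per channel), the true
#' dissociation constant driving the per-cell binding equilibrium, the
#' calibrated detection volume, the curve noise scale, and the number of
#' repeat measurement segments per cell (acquisitions are split into short
#' repeats; five 2-second segments per cell is the default design).
#'
#' @param n_cells Number of cells (>= 1; a typical study measures >= 30
#'   cells per pair).
#' @param expression_log10_mean,expression_log10_sd Length-2 vectors
#'   (green, red): mean and sd of log10 total concentration in nM.
#' @param kd_true True dissociation constant (nM).
#' @param volume A [confocal_volume()].
#' @param noise_sd_scale Dimensionless curve-noise scale; 0 gives
#'   noise-free curves.
#' @param n_segments Measurement segments per cell; the per-lag noise sd
#'   scales as `1/sqrt(n_segments)`.
#' @param seed Integer seed; identical configurations reproduce identical
#'   populations.
#' @return An object of class `fccs_sim_config`.
#' @export
fccs_sim_config <- function(n_cells = 30,
                            expression_log10_mean = c(3, 3),
                            expression_log10_sd = c(0.5, 0.5),
                            kd_true = 1000,
                            volume = confocal_volume(v_eff = 0.25, s = 5,
                                                     w0 = 0.2),
                            noise_sd_scale = 0.02,
                            n_segments = 5,
                            seed = 1L) {
  if (n_cells < 1) stop("fccs_sim_config: n_cells must be >= 1")
  if (noise_sd_scale < 0) stop("fccs_sim_config: noise_sd_scale must be >= 0")
  if (n_segments < 1) stop("fccs_sim_config: n_segments must be >= 1")
  if (kd_true < 0) stop("fccs_sim_config: kd_true must be >= 0")
  stopifnot(inherits(volume, "confocal_volume"),
            length(expression_log10_mean) == 2,
            length(expression_log10_sd) == 2,
            all(expression_log10_sd >= 0))
  structure(list(n_cells = as.integer(n_cells),
                 expression_log10_mean = expression_log10_mean,
                 expression_log10_sd = expression_log10_sd,
                 kd_true = kd_true, volume = volume,
                 noise_sd_scale = noise_sd_scale,
                 n_segments = as.integer(n_segments),
                 seed = as.integer(seed)),
            class = "fccs_sim_config")
}

#' Diffusion and photophysics parameters for simulated curves
#'
#' @param tau_free_green,tau_free_red Diffusion times (s) of the free
#'   tagged species.
#' @param tau_complex Diffusion time (s) of the bound complex (slower than
#'   either free species).
#' @param triplet_fraction,tau_triplet Triplet (dark-state) parameters of
#'   the autocorrelation channels.
#' @param lags Lag ladder (s); defaults to a multi-tau ladder from 1 us to
#'   about 2 s.
#' @return A plain list consumed by [simulate_fccs_curves()].
#' @export
fccs_model_params <- function(tau_free_green = 5e-4, tau_free_red = 5e-4,
                              tau_complex = 1.5e-3,
                              triplet_fraction = 0.15, tau_triplet = 5e-6,
                              lags = make_lag_ladder(1e-6, 17, 16)) {
  if (tau_free_green <= 0 || tau_free_red <= 0 || tau_complex <= 0) {
    stop("fccs_model_params: diffusion times must be > 0")
  }
  list(tau_free_green = tau_free_green, tau_free_red = tau_free_red,
       tau_complex = tau_complex, triplet_fraction = triplet_fraction,
       tau_triplet = tau_triplet, lags = lags)
}

# analytic triple of curves implied by an equilibrium state
.analytic_curves <- function(state, volume, mp) {
  lags <- mp$lags
  s <- volume$s
  n_g <- .molecules_per_veff(state$c_g_total, volume$v_eff)
  n_r <- .molecules_per_veff(state$c_r_total, volume$v_eff)
  f_bound_g <- if (state$c_g_total > 0) state$c_complex / state$c_g_total else 0
  f_bound_r <- if (state$c_r_total > 0) state$c_complex / state$c_r_total else 0

  auto <- function(n, f_bound, tau_free) {
    trip <- 1 + (mp$triplet_fraction / (1 - mp$triplet_fraction)) *
      exp(-lags / mp$tau_triplet)
    trip * .diffusion_term(lags, 1 - f_bound, tau_free, mp$tau_complex, s) / n
  }
  g_green <- auto(n_g, f_bound_g, mp$tau_free_green)
  g_red <- auto(n_r, f_bound_r, mp$tau_free_red)

  # cross amplitude G0 = c_complex / (V N_A c_g c_r); complex diffusion only
  g0_cross <- if (state$c_complex > 0) {
    .molecules_per_veff(state$c_complex, volume$v_eff) / (n_g * n_r)
  } else 0
  g_cross <- g0_cross * .diffusion_term(lags, 0, mp$tau_complex,
                                        mp$tau_complex, s)
  list(green_auto = g_green, red_auto = g_red, cross = g_cross,
       tau_mean_green = (1 - f_bound_g) * mp$tau_free_green + f_bound_g * mp$tau_complex,
       tau_mean_red = (1 - f_bound_r) * mp$tau_free_red + f_bound_r * mp$tau_complex,
       tau_mean_cross = mp$tau_complex)
}

#' Simulate an FCCS curve triple for one cell
#'
#' Evaluates the analytic auto- and cross-correlation models at the
#' equilibrium implied by `state` and adds zero-mean Gaussian per-lag noise
#' with standard deviation
#' `noise_sd_scale * (G(0)/sqrt(n_segments)) * (1 + tau/tau_D)^(-1/2)`,
#' where `tau_D` is the amplitude-weighted mean diffusion time of the
#' curve. The same sd is stored in the `sem` column, so fit weights are
#' well defined. With `noise_sd_scale = 0` the curves equal the analytic
#' models exactly.
#'
#' @param state An [solve_equilibrium()] result.
#' @param cfg An [fccs_sim_config()].
#' @param model_params An [fccs_model_params()] list.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream
#'   (used internally by [simulate_cell_population()]).
#' @param meta Metadata attached to each curve.
#' @return Named list of three [correlation_curve()] objects:
#'   `green_auto`, `red_auto`, `cross`.
#' @export
simulate_fccs_curves <- function(state, cfg, model_params = fccs_model_params(),
                                 seed = cfg$seed, meta = list()) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(cfg, "fccs_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ana <- .analytic_curves(state, cfg$volume, model_params)
  lags <- model_params$lags
  mk <- function(channel, g, tau_mean) {
    g0 <- g[1]
    sd_lag <- if (cfg$noise_sd_scale > 0 && g0 > 0) {
      cfg$noise_sd_scale * (g0 / sqrt(cfg$n_segments)) /
        sqrt(1 + lags / tau_mean)
    } else rep(0, length(lags))
    noisy <- g + stats::rnorm(length(lags), 0, 1) * sd_lag
    correlation_curve(channel, lags, noisy, sem = sd_lag, meta = meta)
  }
  list(green_auto = mk("green_auto", ana$green_auto, ana$tau_mean_green),
       red_auto = mk("red_auto", ana$red_auto, ana$tau_mean_red),
       cross = mk("cross", ana$cross, ana$tau_mean_cross))
}

#' Simulate a single-cell FCCS population with known ground truth
#'
#' Draws per-cell total concentrations log-normally per channel, solves the
#' 1:1 equilibrium at the configured true dissociation constant, and
#' simulates a noisy curve triple per cell. The returned ground truth makes
#' the population usable for parameter-recovery studies.
#'
#' @param cfg An [fccs_sim_config()].
#' @param model_params An [fccs_model_params()] list.
#' @return A list with `cells` (per cell: `curves`, `truth` (the
#'   [solve_equilibrium()] state), `meta`) and the generating `cfg`.
#' @export
simulate_cell_population <- function(cfg, model_params = fccs_model_params()) {
  stopifnot(inherits(cfg, "fccs_sim_config"))
  set.seed(cfg$seed)
  cells <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    c_g <- 10^stats::rnorm(1, cfg$expression_log10_mean[1],
                           cfg$expression_log10_sd[1])
    c_r <- 10^stats::rnorm(1, cfg$expression_log10_mean[2],
                           cfg$expression_log10_sd[2])
    truth <- solve_equilibrium(c_g, c_r, cfg$kd_true)
    meta <- list(cell_id = i, compartment = "cytoplasm",
                 count_rate_kHz = c(green = 100, red = 100),
                 cpm_kHz = c(green = 1, red = 1))
    curves <- simulate_fccs_curves(truth, cfg, model_params, seed = NULL,
                                   meta = meta)
    cells[[i]] <- list(curves = curves, truth = truth, meta = meta)
  }
  list(cells = cells, cfg = cfg, model_params = model_params)
}
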