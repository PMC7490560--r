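#' Normalised interaction ratio (NIR) of a DULIP well
#'
#' In a dual-luminescence co-immunoprecipitation well the Renilla-tagged
#' bait is captured on the plate and the firefly-tagged prey co-precipitates
#' if it binds. The normalised interaction ratio relates the bound
#' firefly/Renilla ratio to the input ratio:
#' `NIR = (fl_bound / rl_bound) / (fl_input / rl_input)`.
#' The ratio is invariant to multiplying all four luminescences of a well
#' by a constant.
#'
#' @param fl_input,rl_input,fl_bound,rl_bound Luminescences (RLU, >= 0);
#'   vectors are accepted and recycled per R rules. Alternatively pass a
#'   data frame with these columns as the first argument.
#' @return Numeric NIR values; wells with a zero denominator yield `NA`
#'   with a warning (excluded, reason reported).
#' @examples
#' compute_nir(fl_input = 100, rl_input = 100, fl_bound = 200, rl_bound = 50)  # 4
#' @export
compute_nir <- function(fl_input, rl_input = NULL, fl_bound = NULL,
                        rl_bound = NULL) {
  if (is.data.frame(fl_input)) {
    d <- fl_input
    fl_input <- d$fl_input; rl_input <- d$rl_input
    fl_bound <- d$fl_bound; rl_bound <- d$rl_bound
  }
  if (any(c(fl_input, rl_input, fl_bound, rl_bound) < 0, na.rm = TRUE)) {
    stop("compute_nir: luminescences must be >= 0")
  }
  bad <- rl_bound <= 0 | rl_input <= 0 | fl_input <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("compute_nir: %d well(s) excluded (zero denominator)",
                    sum(bad, na.rm = TRUE)))
  }
  out <- (fl_bound / rl_bound) / (fl_input / rl_input)
  out[bad | is.na(bad)] <- NA_real_
  out
}

#' Corrected normalised interaction ratio (cNIR)
#'
#' The NIR of a sample pair divided by the NIR of a negative-control pair
#' measured alongside it; a cNIR of 1 means no enrichment over background
#' binding.
#'
#' @param nir_sample NIR of the sample pair.
#' @param nir_negative_control NIR of the negative-control pair (> 0).
#' @return Numeric cNIR values; non-positive controls yield `NA` with a
#'   warning.
#' @export
compute_cnir <- function(nir_sample, nir_negative_control) {
  bad <- !is.finite(nir_negative_control) | nir_negative_control <= 0
  if (any(bad)) {
    warning(sprintf("compute_cnir: %d value(s) excluded (non-positive control)",
                    sum(bad)))
  }
  out <- nir_sample / nir_negative_control
  out[bad] <- NA_real_
  out
}

#' Estimate a DULIP dissociation constant from a saturation series
#'
#' Reconstructs a saturation-binding fit on luminescence proxies: the
#' capture-normalised bound signal `b = fl_bound / (alpha * rl_bound)` is
#' modelled as `b = b_max * S / (S + K)` against the free-prey signal
#' `S = fl_input - beta * fl_bound`. Because `b_max` is fitted jointly, the
#' estimated `K` is invariant to the capture/Renilla gain `alpha` (it is
#' kept as an explicit argument only so alternative normalisations can be
#' swapped in). `K` is expressed in the same (assay-specific) units as the
#' firefly input signal; [apply_scaling()] converts it to molar units.
#'
#' @param wells Data frame with columns `fl_input`, `rl_input`, `fl_bound`,
#'   `rl_bound` (one row per well).
#' @param alpha Capture-normalisation gain on `rl_bound` (default 1).
#' @param beta Depletion coefficient converting bound firefly signal to the
#'   input scale (default 1: input and bound firefly signals share a gain).
#' @param min_fold_range Required fold-range of the free-prey signal.
#' @return Object of class `dulip_kd_estimate`: `kd_dulip`, `sem`, `n`,
#'   `b_max`, `scaled_kd_nM` (`NA` until scaled), `sentinel` (TRUE when no
#'   saturation trend is detectable; `kd_dulip` is then `Inf`).
#' @export
estimate_dulip_kd <- function(wells, alpha = 1, beta = 1,
                              min_fold_range = 5) {
  stopifnot(is.data.frame(wells),
            all(c("fl_input", "rl_bound", "fl_bound") %in% names(wells)))
  n <- nrow(wells)
  if (n < 3) stop("estimate_dulip_kd: need at least 3 wells")
  b <- wells$fl_bound / (alpha * wells$rl_bound)
  S <- wells$fl_input - beta * wells$fl_bound
  ok <- is.finite(b) & is.finite(S) & S > 0
  b <- b[ok]; S <- S[ok]
  if (length(b) < 3) stop("estimate_dulip_kd: fewer than 3 usable wells")
  if (max(S) / min(S) < min_fold_range) {
    stop(sprintf("estimate_dulip_kd: free-prey signal spans < %g-fold range",
                 min_fold_range))
  }
  sentinel <- function() {
    structure(list(kd_dulip = Inf, sem = NA_real_, n = length(b),
                   b_max = NA_real_, scaled_kd_nM = NA_real_,
                   sentinel = TRUE),
              class = "dulip_kd_estimate")
  }
  # no saturation trend: flat or non-increasing bound signal
  if (max(b) <= 0) return(sentinel())
  if (diff(range(b)) <= 0.05 * max(abs(b))) return(sentinel())
  if (!isTRUE(stats::cor(S, b) > 0)) return(sentinel())

  # fit on log scale for positivity; start K at the signal midrange
  resid_fn <- function(theta) {
    bmax <- exp(theta[1]); k <- exp(theta[2])
    b - bmax * S / (S + k)
  }
  start <- c(log(max(b)), log(stats::median(S)))
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(sentinel())
  k_hat <- exp(fit$par[2])
  if (k_hat > 100 * max(S)) return(sentinel())  # no curvature reached
  sem <- tryCatch({
    sigma2 <- fit$deviance / max(length(b) - 2, 1)
    cv <- sigma2 * solve(fit$hessian)
    k_hat * sqrt(cv[2, 2])  # delta method from log-scale
  }, error = function(e) NA_real_)
  structure(list(kd_dulip = k_hat, sem = sem, n = length(b),
                 b_max = exp(fit$par[1]), scaled_kd_nM = NA_real_,
                 sentinel = FALSE),
            class = "dulip_kd_estimate")
}

#' @export
print.dulip_kd_estimate <- function(x, ...) {
  if (x$sentinel) {
    cat(sprintf("DULIP Kd: no saturation trend (n = %d wells); K unbounded\n", x$n))
  } else {
    cat(sprintf("DULIP Kd = %.4g +/- %.3g (assay units), n = %d wells\n",
                x$kd_dulip, x$sem, x$n))
    if (is.finite(x$scaled_kd_nM)) {
      cat(sprintf("  scaled: %.4g nM\n", x$scaled_kd_nM))
    }
  }
  invisible(x)
}

#' One-sample test of a mutant-vs-wild-type interaction effect
#'
#' Tests whether log2-transformed mutant/WT cNIR ratios differ from zero
#' (no effect) with a two-sided one-sample t-test. Technical triplicates
#' are averaged per independent experiment before testing, so `n` is the
#' number of independent experiments. A zero-variance sample is handled
#' degenerately rather than through the t distribution: p = 1 when the
#' common value is 0, otherwise p = 0 with a `degenerate` flag.
#'
#' @param cnir_ratios Mutant-over-WT cNIR values (positive), one per
#'   experiment, or a data frame with columns `experiment` and `cnir` whose
#'   replicates are averaged (geometric mean) within experiment first.
#' @return List with `t`, `df`, `p`, `mean_log2`, `n`, `degenerate`.
#' @export
test_mutant_effect <- function(cnir_ratios) {
  if (is.data.frame(cnir_ratios)) {
    stopifnot(all(c("experiment", "cnir") %in% names(cnir_ratios)))
    cnir_ratios <- tapply(cnir_ratios$cnir, cnir_ratios$experiment,
                          function(v) exp(mean(log(v))))
  }
  x <- log2(as.numeric(cnir_ratios))
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("test_mutant_effect: need >= 2 independent experiments")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p = if (m == 0) 1 else 0, mean_log2 = m, n = n,
                degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1),
       mean_log2 = m, n = n, degenerate = FALSE)
}
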