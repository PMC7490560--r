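#' Fit a correlation curve by weighted Levenberg-Marquardt least squares
#'
#' Fits the two-component 3D-diffusion model ([eval_autocorr_model()]) to a
#' measured correlation curve. Autocorrelation curves (`model = "auto"`)
#' include the triplet correction; cross-correlation curves
#' (`model = "cross"`) are fitted without it. Residuals are weighted by
#' `1/sem` when per-lag uncertainties are available, otherwise the fit is
#' unweighted. The fit is started from data-driven initial values (zero-lag
#' amplitude from the three smallest lags, diffusion time from the
#' half-amplitude lag) plus a small set of dispersed restarts; the restart
#' with the lowest weighted sum of squares is returned.
#'
#' @param curve A [correlation_curve()].
#' @param model `"auto"` (with triplet term) or `"cross"` (triplet forced
#'   to zero).
#' @param volume A [confocal_volume()] supplying the structure parameter.
#' @param n_components 1 or 2 diffusing components.
#' @param fit_offset Fit an additive baseline (default `TRUE`).
#' @param init Optional named list overriding the automatic initial values
#'   (`n_particles`, `f_fast`, `tau_d_fast`, `tau_d_slow`,
#'   `triplet_fraction`, `tau_triplet`, `offset`).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#'
#' @return An object of class `fccs_fit`: a list with `params` (a
#'   [diffusion_params()] carrying the estimate covariance), `converged`
#'   (logical; `FALSE` results are flagged, never raised as errors),
#'   `flags` (character reason codes), `deviance`, `dof`, `model`, and the
#'   fitted curve values `fitted`.
#' @export
fit_correlation_curve <- function(curve, model = c("auto", "cross"),
                                  volume, n_components = 2,
                                  fit_offset = TRUE, init = NULL,
                                  maxiter = 200) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(volume, "confocal_volume"))
  lags <- curve$lags
  g <- curve$g
  with_triplet <- (model == "auto")
  n_free <- 1 + (n_components == 2) * 3 + with_triplet * 2 + fit_offset
  if (length(lags) < 8 * n_free) {
    stop("fit_correlation_curve: need at least 8 lags per free parameter")
  }

  w <- rep(1, length(lags))
  if (any(curve$sem > 0)) {
    pos <- curve$sem > 0
    w[pos] <- 1 / curve$sem[pos]
    w[!pos] <- stats::median(w[pos])
  }

  auto_init <- .curve_init(lags, g)
  if (!is.null(init)) auto_init[names(init)] <- init

  # free-parameter layout (log scale for positive quantities)
  free <- c("n_particles", if (n_components == 2) c("f_fast", "tau_d_fast", "tau_d_slow") else "tau_d_fast",
            if (with_triplet) c("triplet_fraction", "tau_triplet"),
            if (fit_offset) "offset")

  pack <- function(v) {
    out <- numeric(0)
    for (nm in free) {
      out <- c(out, switch(nm,
        n_particles = log(v$n_particles),
        f_fast = stats::qlogis(min(max(v$f_fast, 1e-4), 1 - 1e-4)),
        tau_d_fast = log(v$tau_d_fast),
        tau_d_slow = log(v$tau_d_slow),
        triplet_fraction = stats::qlogis(min(max(v$triplet_fraction, 1e-5), 0.999)),
        tau_triplet = log(v$tau_triplet),
        offset = v$offset))
    }
    out
  }
  unpack <- function(theta) {
    v <- auto_init
    for (i in seq_along(free)) {
      nm <- free[i]
      v[[nm]] <- switch(nm,
        n_particles = exp(theta[i]),
        f_fast = stats::plogis(theta[i]),
        tau_d_fast = exp(theta[i]),
        tau_d_slow = exp(theta[i]),
        triplet_fraction = stats::plogis(theta[i]),
        tau_triplet = exp(theta[i]),
        offset = theta[i])
    }
    if (n_components == 1) {
      v$f_fast <- 1; v$tau_d_slow <- v$tau_d_fast
    }
    if (!with_triplet) v$triplet_fraction <- 0
    if (!fit_offset) v$offset <- 0
    v
  }
  model_eval <- function(v) {
    s <- volume$s
    trip <- if (v$triplet_fraction > 0) {
      1 + (v$triplet_fraction / (1 - v$triplet_fraction)) * exp(-lags / v$tau_triplet)
    } else 1
    v$offset + trip * .diffusion_term(lags, v$f_fast, v$tau_d_fast,
                                      v$tau_d_slow, s) / v$n_particles
  }
  resid_fn <- function(theta) w * (g - model_eval(unpack(theta)))

  # physical box constraints on the transformed scale; notably the triplet
  # relaxation time is confined to the microsecond regime so it cannot
  # degenerate into a constant amplitude factor traded off against N
  bound_of <- function(nm, side) {
    switch(nm,
      n_particles = if (side == 1) log(1e-6) else log(1e9),
      f_fast = if (side == 1) -30 else 30,
      tau_d_fast = ,
      tau_d_slow = if (side == 1) log(min(lags) / 10) else log(max(lags) * 10),
      triplet_fraction = if (side == 1) -30 else 30,
      tau_triplet = if (side == 1) log(1e-7) else log(1e-4),
      offset = if (side == 1) -Inf else Inf)
  }
  lower <- vapply(free, bound_of, numeric(1), side = 1)
  upper <- vapply(free, bound_of, numeric(1), side = 2)

  starts <- .fit_starts(auto_init, n_components, with_triplet)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(pack(st), lower), upper),
                         fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("fit_correlation_curve: all Levenberg-Marquardt starts failed")
  }

  flags <- character(0)
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "non-convergence")

  v <- unpack(best$par)
  # canonical component order: fast before slow
  if (n_components == 2 && v$tau_d_fast > v$tau_d_slow) {
    tmp <- v$tau_d_fast; v$tau_d_fast <- v$tau_d_slow; v$tau_d_slow <- tmp
    v$f_fast <- 1 - v$f_fast
  }

  dof <- length(lags) - length(free)
  sigma2 <- best$deviance / max(dof, 1)
  covar <- tryCatch({
    cv <- sigma2 * solve(best$hessian)
    dimnames(cv) <- list(free, free)
    cv
  }, error = function(e) {
    flags <<- c(flags, "singular-covariance")
    NULL
  })

  params <- diffusion_params(
    n_particles = v$n_particles, f_fast = v$f_fast,
    tau_d_fast = v$tau_d_fast, tau_d_slow = v$tau_d_slow,
    triplet_fraction = v$triplet_fraction, tau_triplet = v$tau_triplet,
    offset = v$offset, covariance = covar)

  structure(list(params = params, converged = converged, flags = flags,
                 deviance = best$deviance, dof = dof, model = model,
                 n_components = n_components,
                 fitted = model_eval(v), curve = curve),
            class = "fccs_fit")
}

# data-driven initial values: amplitude from the 3 smallest lags, baseline
# from the 3 largest, diffusion time from the half-amplitude lag
.curve_init <- function(lags, g) {
  off0 <- mean(utils::tail(g, 3))
  g0 <- mean(utils::head(g, 3)) - off0
  if (!is.finite(g0) || g0 <= 0) g0 <- max(g - off0, 1e-6)
  half <- off0 + g0 / 2
  tau_half <- lags[which.min(abs(g - half))]
  if (tau_half <= min(lags)) tau_half <- stats::median(lags)
  list(n_particles = 1 / g0, f_fast = 0.5,
       tau_d_fast = tau_half / 4, tau_d_slow = tau_half * 4,
       triplet_fraction = 0.1, tau_triplet = 5e-6, offset = off0)
}

.fit_starts <- function(init, n_components, with_triplet) {
  starts <- list(init)
  if (n_components == 2) {
    s2 <- init; s2$tau_d_fast <- init$tau_d_fast / 4; s2$tau_d_slow <- init$tau_d_slow * 4
    s3 <- init; s3$f_fast <- 0.8
    s4 <- init; s4$f_fast <- 0.2
    starts <- c(starts, list(s2, s3, s4))
  }
  if (with_triplet) {
    s5 <- init; s5$triplet_fraction <- 0.02; s5$tau_triplet <- 2e-6
    starts <- c(starts, list(s5))
  }
  starts
}

#' @export
print.fccs_fit <- function(x, ...) {
  cat(sprintf("FCCS %scorrelation fit (%d component%s)%s\n",
              if (x$model == "cross") "cross-" else "auto",
              x$n_components, if (x$n_components > 1) "s" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  cat(sprintf("  weighted SSR = %.4g on %d dof\n", x$deviance, x$dof))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fccs_fit <- function(object, ...) {
  p <- object$params
  c(n_particles = p$n_particles, f_fast = p$f_fast,
    tau_d_fast = p$tau_d_fast, tau_d_slow = p$tau_d_slow,
    triplet_fraction = p$triplet_fraction, tau_triplet = p$tau_triplet,
    offset = p$offset)
}

#' @export
fitted.fccs_fit <- function(object, ...) object$fitted

#' @export
residuals.fccs_fit <- function(object, ...) object$curve$g - object$fitted
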