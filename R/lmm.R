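# Profiled-REML machinery for a single-random-intercept linear mixed model
#
# y = X beta + Z u + e,  u ~ N(0, sigma_p^2 I_q),  e ~ N(0, sigma_e^2 I_n)
# V = sigma_e^2 (I + lambda Z Z'),  lambda = sigma_p^2 / sigma_e^2.
# For fixed lambda the GLS beta and sigma_e^2 have closed forms, leaving a
# one-dimensional REML criterion in lambda.

# restricted log-likelihood at variance components th = (sigma_p2, sigma_e2)
.reml_loglik <- function(th, y, X, Z) {
  n <- nrow(X); p <- ncol(X)
  V <- th[2] * diag(n) + th[1] * tcrossprod(Z)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XVX <- crossprod(X, Vi_X)
  beta <- solve(XVX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * Vi_r)
  logdetV <- 2 * sum(log(diag(ch)))
  logdetXVX <- as.numeric(determinant(XVX, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXVX + quad))
}

# profiled criterion: given lambda, sigma_e2 is profiled out analytically
.profile_reml <- function(lambda, y, X, Z) {
  n <- nrow(X); p <- ncol(X)
  Vs <- diag(n) + lambda * tcrossprod(Z)
  ch <- tryCatch(chol(Vs), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XVX <- crossprod(X, Vi_X)
  beta <- solve(XVX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * Vi_r)
  sigma_e2 <- quad / (n - p)
  crit <- 2 * sum(log(diag(ch))) +
    as.numeric(determinant(XVX, logarithm = TRUE)$modulus) +
    (n - p) * log(sigma_e2)
  list(crit = crit, beta = beta, sigma_e2 = sigma_e2, XVX = XVX)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits `log2_fc ~ condition * cell_line` (or any user formula) with a
#' single random intercept per plate. The restricted likelihood is
#' maximised by one-dimensional optimisation over the variance ratio
#' `sigma_plate^2 / sigma_resid^2` with the fixed effects and the residual
#' variance profiled out; the boundary `sigma_plate^2 = 0` is always
#' evaluated and wins ties, so variance estimates are non-negative by
#' construction. When the plate variance is zero the fixed-effect
#' estimates coincide with ordinary least squares.
#'
#' @param data Data frame containing the response, the fixed-effect
#'   covariates, and the grouping column.
#' @param fixed Fixed-effects formula (response on the left); default
#'   `log2_fc ~ condition * cell_line`.
#' @param group Name of the random-intercept grouping column (default
#'   `"plate"`).
#' @return Object of class `reporter_lmm`: `beta` (named), `se`,
#'   `vcov_beta`, `sigma_plate2`, `sigma_resid2`, `reml_loglik`, `n`, `p`,
#'   plus the design matrices for downstream contrasts.
#' @export
fit_reporter_lmm <- function(data, fixed = log2_fc ~ condition * cell_line,
                             group = "plate") {
  stopifnot(is.data.frame(data), group %in% names(data))
  mf <- stats::model.frame(fixed, data = droplevels(data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("fit_reporter_lmm: need >= 2 grouping levels")
  Z <- stats::model.matrix(~ 0 + g)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("fit_reporter_lmm: design not full rank; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  obj <- function(loglam) .profile_reml(exp(loglam), y, X, Z)$crit
  opt <- stats::optimize(obj, c(-15, 15), tol = 1e-10)
  cand <- c(0, exp(opt$minimum))
  crits <- vapply(cand, function(l) .profile_reml(l, y, X, Z)$crit, numeric(1))
  lambda <- cand[which.min(crits)]
  prof <- .profile_reml(lambda, y, X, Z)
  sigma_e2 <- prof$sigma_e2
  sigma_p2 <- lambda * sigma_e2
  vcov_beta <- sigma_e2 * solve(prof$XVX)
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  structure(list(beta = beta, se = sqrt(diag(vcov_beta)),
                 vcov_beta = vcov_beta,
                 sigma_plate2 = sigma_p2, sigma_resid2 = sigma_e2,
                 reml_loglik = .reml_loglik(c(sigma_p2, sigma_e2), y, X, Z),
                 n = nrow(X), p = ncol(X), q = ncol(Z),
                 y = y, X = X, Z = Z, fixed = fixed, group = group),
            class = "reporter_lmm")
}

#' @export
print.reporter_lmm <- function(x, ...) {
  cat("random-intercept linear mixed model (REML)\n")
  cat(sprintf("  n = %d, fixed effects = %d, groups = %d\n", x$n, x$p, x$q))
  cat(sprintf("  sigma_plate^2 = %.4g, sigma_resid^2 = %.4g, REML logLik = %.4f\n",
              x$sigma_plate2, x$sigma_resid2, x$reml_loglik))
  est <- cbind(estimate = x$beta, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' @export
coef.reporter_lmm <- function(object, ...) object$beta

#' @export
vcov.reporter_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.reporter_lmm <- function(object, ...) {
  structure(object$reml_loglik, df = object$p + 2, class = "logLik")
}

#' Satterthwaite-approximated t-test of a fixed-effect contrast
#'
#' For contrast `c` the statistic is
#' `t = c' beta / sqrt(c' V(theta) c)` with
#' `V(theta) = (X' Sigma(theta)^-1 X)^-1`. The effective degrees of
#' freedom follow Satterthwaite's method:
#' `df = 2 f(theta)^2 / (g' A g)` where `f(theta) = c' V(theta) c`, `g` is
#' its gradient in the variance components (central finite differences),
#' and `A` is the asymptotic covariance of the variance-component
#' estimates (inverse observed REML information). At the boundary
#' `sigma_plate^2 = 0` the classical residual degrees of freedom `n - p`
#' are returned.
#'
#' @param fit A [fit_reporter_lmm()] object.
#' @param contrast Numeric contrast vector (length `fit$p`) or the name of
#'   a fixed-effect coefficient.
#' @return List with `estimate`, `se`, `t`, `df`, `p`.
#' @export
satterthwaite_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "reporter_lmm"))
  if (is.character(contrast)) {
    stopifnot(contrast %in% names(fit$beta))
    cvec <- as.numeric(names(fit$beta) == contrast)
  } else {
    cvec <- as.numeric(contrast)
  }
  if (length(cvec) != fit$p) {
    stop("satterthwaite_contrast: contrast length must match fixed effects")
  }
  if (all(cvec == 0)) stop("satterthwaite_contrast: zero contrast")

  est <- sum(cvec * fit$beta)
  X <- fit$X; Z <- fit$Z; y <- fit$y
  n <- fit$n; p <- fit$p

  f_of <- function(th) {
    V <- th[2] * diag(n) + th[1] * tcrossprod(Z)
    Vi_X <- solve(V, X)
    drop(t(cvec) %*% solve(crossprod(X, Vi_X), cvec))
  }
  th <- c(fit$sigma_plate2, fit$sigma_resid2)
  f_hat <- f_of(th)
  se <- sqrt(f_hat)
  tstat <- est / se

  boundary <- th[1] < 1e-8 * th[2]
  if (boundary) {
    df <- n - p
  } else {
    # gradient of f in theta (central differences, relative step)
    grad <- vapply(1:2, function(j) {
      h <- 1e-6 * th[j]
      tp <- th; tm <- th
      tp[j] <- th[j] + h; tm[j] <- th[j] - h
      (f_of(tp) - f_of(tm)) / (2 * h)
    }, numeric(1))
    # observed REML information (Hessian of the negative loglik)
    nll <- function(t2) -.reml_loglik(t2, y, X, Z)
    H <- matrix(NA_real_, 2, 2)
    hstep <- 1e-4 * th
    for (j in 1:2) for (k in j:2) {
      tpp <- th; tpm <- th; tmp <- th; tmm <- th
      tpp[j] <- tpp[j] + hstep[j]; tpp[k] <- tpp[k] + hstep[k]
      tpm[j] <- tpm[j] + hstep[j]; tpm[k] <- tpm[k] - hstep[k]
      tmp[j] <- tmp[j] - hstep[j]; tmp[k] <- tmp[k] + hstep[k]
      tmm[j] <- tmm[j] - hstep[j]; tmm[k] <- tmm[k] - hstep[k]
      H[j, k] <- H[k, j] <-
        (nll(tpp) - nll(tpm) - nll(tmp) + nll(tmm)) /
        (4 * hstep[j] * hstep[k])
    }
    A <- tryCatch(solve(H), error = function(e) NULL)
    df <- if (is.null(A)) n - p else {
      denom <- drop(t(grad) %*% A %*% grad)
      if (denom <= 0) n - p else 2 * f_hat^2 / denom
    }
    df <- min(max(df, 1), n - p)
  }
  list(estimate = est, se = se, t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Bonferroni multiple-testing adjustment
#'
#' `p_adj = min(1, m * p)`; order-preserving and clamped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Number of tests (default `length(pvals)`).
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("adjust_bonferroni: p-values must lie in [0, 1]")
  }
  pmin(1, m * pvals)
}
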