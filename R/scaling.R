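#' Cross-platform scaling of DULIP dissociation constants to molar units
#'
#' Ordinary least squares of `Y = log10(kd_fccs_nM)` on
#' `X = log10(kd_dulip)` over partners measured on both platforms, plus the
#' Pearson correlation (with its two-sided p-value) as the concordance
#' measure. The fitted line converts assay-unit DULIP constants to
#' equivalent molar (nM) values via [apply_scaling()].
#'
#' @param pairs Data frame with positive columns `kd_dulip` and
#'   `kd_fccs_nM`, one row per partner quantified on both platforms.
#' @return Object of class `scaling_model`: `slope`, `intercept` (log10
#'   scale), `pearson_r`, `p_value`, `n`.
#' @export
fit_cross_platform_scaling <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("kd_dulip", "kd_fccs_nM") %in% names(pairs)))
  ok <- is.finite(pairs$kd_dulip) & is.finite(pairs$kd_fccs_nM) &
    pairs$kd_dulip > 0 & pairs$kd_fccs_nM > 0
  d <- pairs[ok, ]
  if (nrow(d) < 3) stop("fit_cross_platform_scaling: need >= 3 positive pairs")
  x <- log10(d$kd_dulip); y <- log10(d$kd_fccs_nM)
  if (stats::sd(x) == 0) {
    stop("fit_cross_platform_scaling: degenerate design (constant X)")
  }
  fit <- stats::lm(y ~ x)
  ct <- if (stats::sd(y) == 0) list(estimate = 0, p.value = 1)
        else stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 scale = "log10",
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = nrow(d), lm = fit),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("cross-platform scaling (log10): Y = %.3f * X + %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.3f (p = %.3g), n = %d pairs\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.scaling_model <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Scale DULIP dissociation constants to molar units
#'
#' Applies a fitted [fit_cross_platform_scaling()] model on the log10
#' scale: `10^(slope * log10(kd_dulip) + intercept)` (nM).
#'
#' @param model A `scaling_model`.
#' @param kd_dulip Positive DULIP dissociation constants (assay units).
#' @return Scaled values in nM.
#' @export
apply_scaling <- function(model, kd_dulip) {
  stopifnot(inherits(model, "scaling_model"))
  if (any(kd_dulip <= 0 | !is.finite(kd_dulip))) {
    stop("apply_scaling: kd_dulip must be positive and finite")
  }
  10^(model$slope * log10(kd_dulip) + model$intercept)
}

#' Invert the cross-platform scaling
#'
#' Maps a molar (nM) value back to DULIP assay units; composing with
#' [apply_scaling()] is the identity.
#'
#' @inheritParams apply_scaling
#' @param kd_nM Positive scaled values (nM).
#' @return DULIP assay-unit values.
#' @export
invert_scaling <- function(model, kd_nM) {
  stopifnot(inherits(model, "scaling_model"))
  if (any(kd_nM <= 0 | !is.finite(kd_nM))) {
    stop("invert_scaling: kd_nM must be positive and finite")
  }
  if (model$slope == 0) stop("invert_scaling: zero slope is not invertible")
  10^((log10(kd_nM) - model$intercept) / model$slope)
}
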