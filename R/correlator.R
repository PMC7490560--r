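#' Construct a correlation curve
#'
#' A correlation curve is the unit object consumed by
#' [fit_correlation_curve()]: a ladder of strictly increasing lag times with
#' a correlation amplitude and a per-lag uncertainty at each lag, plus
#' acquisition metadata.
#'
#' @param channel One of `"green_auto"`, `"red_auto"`, `"cross"`.
#' @param lags Lag times in seconds, strictly increasing.
#' @param g Correlation amplitudes, same length as `lags`.
#' @param sem Per-lag standard errors (>= 0), same length as `lags`.
#' @param meta Named list of metadata (cell id, compartment, count rates in
#'   kHz, counts per molecule in kHz, ...).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(channel, lags, g, sem = rep(0, length(lags)),
                              meta = list()) {
  channel <- match.arg(channel, c("green_auto", "red_auto", "cross"))
  lags <- as.numeric(lags); g <- as.numeric(g); sem <- as.numeric(sem)
  if (length(lags) != length(g) || length(g) != length(sem)) {
    stop("correlation_curve: lags, g and sem must have equal length")
  }
  if (length(lags) == 0L || any(!is.finite(lags)) || any(diff(lags) <= 0)) {
    stop("correlation_curve: lags must be finite and strictly increasing")
  }
  if (any(sem < 0) || any(is.na(sem))) {
    stop("correlation_curve: sem must be non-negative")
  }
  structure(list(channel = channel, lags = lags, g = g, sem = sem,
                 meta = meta),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve [%s]: %d lags, %.3g s .. %.3g s, G(first) = %.4g\n",
              x$channel, length(x$lags), min(x$lags), max(x$lags), x$g[1]))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, G = x$g, sem = x$sem)
}

#' Multi-tau lag ladder
#'
#' Builds the quasi-logarithmic lag ladder used by multi-tau correlators:
#' `m_per_level` linearly spaced lags at the base resolution, then
#' `m_per_level / 2` lags per level with the lag spacing doubling at each
#' level.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param n_levels Number of coarsening levels beyond the base level.
#' @param m_per_level Lags in the base level (even, >= 4).
#' @param max_lag Optional cap on the largest lag (seconds).
#' @return Numeric vector of lag times in seconds (strictly increasing).
#' @export
make_lag_ladder <- function(dt, n_levels = 8, m_per_level = 16,
                            max_lag = Inf) {
  if (!is.finite(dt) || dt <= 0) stop("make_lag_ladder: dt must be > 0")
  if (m_per_level < 4 || m_per_level %% 2 != 0) {
    stop("make_lag_ladder: m_per_level must be an even number >= 4")
  }
  ks <- seq_len(m_per_level)
  for (lev in seq_len(n_levels)) {
    step <- 2^lev
    ks <- c(ks, seq((m_per_level / 2) * step + step, m_per_level * step,
                    by = step))
  }
  lags <- ks * dt
  lags[lags <= max_lag]
}

# exact normalised fluctuation correlation at integer sample lags
.correlate_at_lags <- function(a, b, lag_samples) {
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  vapply(lag_samples, function(k) {
    idx <- seq_len(n - k)
    mean(a[idx] * b[idx + k]) / (ma * mb) - 1
  }, numeric(1))
}

#' Multi-tau correlation of intensity traces
#'
#' Computes the normalised fluctuation correlation
#' \deqn{G(\tau) = \langle \delta a(t)\, \delta b(t+\tau) \rangle /
#'   (\langle a \rangle \langle b \rangle)}
#' on a multi-tau (quasi-logarithmic) lag ladder. Passing the same trace
#' twice (the default for `trace_b`) yields the autocorrelation. At every
#' ladder lag the estimator is evaluated exactly on the raw trace, so the
#' values are free of the coarse-graining bias of running-average
#' correlator hardware; the ladder only sets which lags are reported.
#' Per-lag uncertainties are estimated by splitting the trace into
#' `n_segments` contiguous segments and taking the standard error of the
#' per-segment estimates.
#'
#' @param trace_a,trace_b Equal-length numeric photon-count (or intensity)
#'   traces. `trace_b` defaults to `trace_a` (autocorrelation).
#' @param dt Sampling interval in seconds.
#' @param m_per_level,n_levels Ladder geometry, see [make_lag_ladder()].
#' @param channel Channel label stored on the returned curve.
#' @param n_segments Segments used for the per-lag sem estimate (set to 1
#'   to skip; sem is then 0).
#' @return A [correlation_curve()] whose meta carries the mean count rates.
#' @export
multitau_correlate <- function(trace_a, trace_b = trace_a, dt,
                               m_per_level = 16, n_levels = NULL,
                               channel = "green_auto", n_segments = 5) {
  a <- as.numeric(trace_a); b <- as.numeric(trace_b)
  n <- length(a)
  if (length(b) != n) stop("multitau_correlate: traces must have equal length")
  if (n < 2 * m_per_level) {
    stop("multitau_correlate: traces must contain at least 2 * m_per_level samples")
  }
  if (abs(mean(a)) < .Machine$double.eps * 1e3 ||
      abs(mean(b)) < .Machine$double.eps * 1e3) {
    stop("multitau_correlate: trace mean is zero; normalisation undefined")
  }
  if (is.null(n_levels)) {
    n_levels <- max(0L, floor(log2(n / (4 * m_per_level))))
  }
  lags <- make_lag_ladder(dt, n_levels, m_per_level, max_lag = (n / 4) * dt)
  ks <- round(lags / dt)
  g <- .correlate_at_lags(a, b, ks)

  sem <- rep(0, length(ks))
  if (n_segments > 1) {
    seg_len <- floor(n / n_segments)
    ok <- ks < seg_len / 2
    if (any(ok)) {
      gs <- sapply(seq_len(n_segments), function(si) {
        idx <- ((si - 1) * seg_len + 1):(si * seg_len)
        .correlate_at_lags(a[idx], b[idx], ks[ok])
      })
      gs <- matrix(gs, nrow = sum(ok))
      sem[ok] <- apply(gs, 1, stats::sd) / sqrt(n_segments)
    }
  }
  correlation_curve(channel, lags, g, sem,
                    meta = list(count_rate_a_kHz = mean(a) / dt / 1000,
                                count_rate_b_kHz = mean(b) / dt / 1000,
                                n_samples = n, dt = dt))
}
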