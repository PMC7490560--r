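#' Solve a 1:1 binding equilibrium
#'
#' Computes the equilibrium complex concentration for a bimolecular
#' interaction `G + R <-> GR` with dissociation constant `kd`, given the
#' total concentrations of both species. The complex concentration is the
#' physical root of the mass-action quadratic
#' \deqn{c^2 - (c_G + c_R + K_d)\,c + c_G c_R = 0,}
#' i.e. the smaller root, which always lies in `[0, min(c_G, c_R)]`.
#'
#' @param c_g_total Total concentration of the green-tagged species (nM).
#' @param c_r_total Total concentration of the red-tagged species (nM).
#' @param kd Dissociation constant (nM). `kd = 0` is the infinite-affinity
#'   limit; very large `kd` approaches the no-binding limit.
#'
#' @return An object of class `equilibrium_state`: a list with fields
#'   `c_g_total`, `c_r_total`, `kd_true`, `c_complex`, `c_g_free`,
#'   `c_r_free` (all nM). Mass balance `free + complex == total` holds to
#'   better than 1e-9 relative, and `c_g_free * c_r_free / c_complex == kd`
#'   to better than 1e-6 relative whenever `c_complex > 0`.
#'
#' @examples
#' eq <- solve_equilibrium(1000, 1000, 1000)
#' eq$c_complex  # (3000 - sqrt(9e6 - 4e6)) / 2 ~= 381.97 nM
#' @export
solve_equilibrium <- function(c_g_total, c_r_total, kd) {
  stopifnot(length(c_g_total) == 1L, length(c_r_total) == 1L, length(kd) == 1L)
  if (!is.finite(c_g_total) || !is.finite(c_r_total) ||
      c_g_total < 0 || c_r_total < 0 || kd < 0 || is.na(kd)) {
    stop("solve_equilibrium: concentrations and kd must be non-negative")
  }
  b <- c_g_total + c_r_total + kd
  # numerically stable smaller quadratic root: 2q/(b + sqrt(b^2 - 4q))
  q <- c_g_total * c_r_total
  disc <- b * b - 4 * q
  disc <- max(disc, 0)
  c_complex <- if (b > 0) 2 * q / (b + sqrt(disc)) else 0
  c_complex <- min(c_complex, c_g_total, c_r_total)
  structure(
    list(
      c_g_total = c_g_total,
      c_r_total = c_r_total,
      kd_true = kd,
      c_complex = c_complex,
      c_g_free = c_g_total - c_complex,
      c_r_free = c_r_total - c_complex
    ),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("1:1 binding equilibrium (nM)\n")
  cat(sprintf("  totals: green %.4g, red %.4g;  Kd = %.4g\n",
              x$c_g_total, x$c_r_total, x$kd_true))
  cat(sprintf("  complex %.4g;  free: green %.4g, red %.4g\n",
              x$c_complex, x$c_g_free, x$c_r_free))
  invisible(x)
}
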