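#' Normalise dual-luciferase reporter wells to log2 fold changes
#'
#' Per well the firefly/Renilla ratio is divided by the geometric mean of
#' the same-plate, same-cell-line empty-vector ratios and log2-transformed.
#' Plates lacking an empty-vector baseline for a cell line contribute no
#' observations for that cell line; if a plate has no baseline at all it is
#' dropped entirely. Exclusions raise a warning naming the plates.
#'
#' @param obs Data frame with columns `plate`, `cell_line`, `condition`,
#'   `fl`, `rl` (both > 0).
#' @param baseline_condition Condition label of the empty-vector wells.
#' @return The retained rows of `obs` with a `log2_fc` column appended.
#' @export
normalise_luciferase <- function(obs, baseline_condition = "empty_vector") {
  need <- c("plate", "cell_line", "condition", "fl", "rl")
  stopifnot(is.data.frame(obs), all(need %in% names(obs)))
  if (any(obs$fl <= 0 | obs$rl <= 0)) {
    stop("normalise_luciferase: fl and rl must be > 0")
  }
  ratio <- obs$fl / obs$rl
  grp <- interaction(obs$plate, obs$cell_line, drop = TRUE)
  base_mean <- tapply(
    ifelse(obs$condition == baseline_condition, log2(ratio), NA_real_),
    grp, mean, na.rm = TRUE)
  has_base <- is.finite(base_mean[as.character(grp)])
  if (!all(has_base)) {
    bad <- unique(obs$plate[!has_base])
    warning(sprintf(
      "normalise_luciferase: no '%s' baseline for plate(s) %s; wells excluded",
      baseline_condition, paste(bad, collapse = ", ")))
  }
  out <- obs[has_base, , drop = FALSE]
  out$log2_fc <- as.numeric(log2(ratio[has_base]) -
                              base_mean[as.character(grp[has_base])])
  out
}
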