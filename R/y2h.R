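#' Score a yeast two-hybrid matrix screen
#'
#' A bait-prey pair (per NRF2 fragment) is scored positive only when
#' growth is observed in at least two independent assay replicates and
#' neither clone is an auto-activator. Growth on either reporter (ADE2 or
#' HIS3) counts as growth for that replicate. Pairs assayed fewer than two
#' times are reported as `untested_incomplete`, never positive;
#' auto-activating clones are `excluded_autoactivator`. Adding a positive
#' replicate can never remove a positive call (the rule is monotone).
#'
#' @param calls Data frame of growth calls with columns `bait`, `prey`,
#'   `nrf2_fragment`, `assay_replicate`, `reporter`, `growth` (logical),
#'   `autoactivator` (logical).
#' @param min_positive_replicates Replicates with growth required for a
#'   positive call (default 2).
#' @return Object of class `y2h_score`: `pairs`, a data frame with one row
#'   per bait/prey/fragment (`n_replicates`, `n_growth_replicates`,
#'   `autoactivator`, `status` in
#'   `positive`/`negative`/`excluded_autoactivator`/`untested_incomplete`),
#'   and `domain_profiles`, a named list mapping each positive prey to its
#'   set of positive NRF2 fragments.
#' @export
score_y2h_matrix <- function(calls, min_positive_replicates = 2) {
  need <- c("bait", "prey", "nrf2_fragment", "assay_replicate", "reporter",
            "growth", "autoactivator")
  stopifnot(is.data.frame(calls), all(need %in% names(calls)))

  key <- interaction(calls$bait, calls$prey, calls$nrf2_fragment,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(calls, key), function(d) {
    # a replicate grows if either reporter grows
    rep_growth <- tapply(d$growth, d$assay_replicate, any)
    n_rep <- length(rep_growth)
    n_grow <- sum(rep_growth)
    auto <- any(d$autoactivator)
    status <- if (n_rep < 2) "untested_incomplete"
      else if (auto) "excluded_autoactivator"
      else if (n_grow >= min_positive_replicates) "positive"
      else "negative"
    data.frame(bait = d$bait[1], prey = d$prey[1],
               nrf2_fragment = d$nrf2_fragment[1],
               n_replicates = n_rep, n_growth_replicates = n_grow,
               autoactivator = auto, status = status)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  pos <- pairs[pairs$status == "positive", , drop = FALSE]
  domain_profiles <- lapply(split(pos$nrf2_fragment, toupper(pos$prey)),
                            function(f) sort(unique(f)))
  structure(list(pairs = pairs, domain_profiles = domain_profiles),
            class = "y2h_score")
}

#' @export
print.y2h_score <- function(x, ...) {
  tab <- table(x$pairs$status)
  cat("Y2H matrix scoring (reproducible-in-two rule)\n")
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}
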