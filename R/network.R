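#' Classify a conditional affinity change between WT and KEAP1-null cells
#'
#' A partner whose dissociation constant changes more than `threshold`-fold
#' between wild-type and KEAP1-null cells is conditionally reclassified:
#' `kd_ko / kd_wt > threshold` is a loss of affinity (weaker binding after
#' KEAP1 knockout), `kd_ko / kd_wt < 1/threshold` a gain. The inequality is
#' strict, so a ratio exactly at the threshold is `unchanged`.
#'
#' @param kd_wt,kd_ko Dissociation constants (> 0) in wild-type and
#'   KEAP1-null cells; vectors are accepted.
#' @param threshold Fold-change threshold (> 1; default 1.25).
#' @return Character vector in `c("gain", "loss", "unchanged")`.
#' @examples
#' classify_conditional_affinity(1000, 2000)  # "loss"
#' classify_conditional_affinity(1000, 1250)  # exactly 1.25-fold: "unchanged"
#' @export
classify_conditional_affinity <- function(kd_wt, kd_ko, threshold = 1.25) {
  if (threshold <= 1) stop("classify_conditional_affinity: threshold must be > 1")
  if (any(!is.finite(kd_wt) | !is.finite(kd_ko) | kd_wt <= 0 | kd_ko <= 0)) {
    stop("classify_conditional_affinity: dissociation constants must be > 0")
  }
  ratio <- kd_ko / kd_wt
  ifelse(ratio > threshold, "loss",
         ifelse(ratio < 1 / threshold, "gain", "unchanged"))
}

.norm_sym <- function(x) toupper(trimws(as.character(x)))

.check_unique <- function(d, what) {
  if (is.null(d)) return(invisible())
  dup <- unique(d$partner[duplicated(d$partner)])
  if (length(dup)) {
    stop(sprintf("integrate_evidence: conflicting duplicate %s records for: %s",
                 what, paste(dup, collapse = ", ")))
  }
}

#' Integrate evidence layers into one interaction record per partner
#'
#' Joins the Y2H matrix score, the co-IP confirmation flags, the FCCS and
#' scaled DULIP dissociation constants (WT and KEAP1-null), the
#' reporter-screen functional class and external annotations into one
#' record per partner, keyed by case-normalised gene symbol. Missing
#' layers are explicit `NA` markers. Partners with both WT and KEAP1-null
#' scaled DULIP constants receive an affinity fold change
#' (`kd_ko / kd_wt`) and a conditional class via
#' [classify_conditional_affinity()].
#'
#' @param y2h A [score_y2h_matrix()] result, or `NULL`.
#' @param coip Data frame `partner`, `confirmed` (logical), or `NULL`.
#' @param fccs Data frame `partner`, `kd_mean`, optionally `ci_lo`,
#'   `ci_hi`, `n_cells`, `binder`, or `NULL`.
#' @param dulip Data frame `partner`, `scaled_kd_wt_nM`,
#'   `scaled_kd_ko_nM` (either may be `NA`), or `NULL`.
#' @param reporter_classes Data frame `partner`, `class` (a single label
#'   or `+`-joined labels), or `NULL`.
#' @param annotations Data frame `partner`, `annotation`, `known_partner`
#'   (logical), or `NULL`.
#' @param threshold Conditional-affinity fold-change threshold.
#' @return Object of class `interaction_records`: a data frame with one
#'   row per partner and columns `partner`, `domains_bound`,
#'   `y2h_positive`, `coip_confirmed`, `kd_fccs_nM`, `kd_dulip_wt_nM`,
#'   `kd_dulip_ko_nM`, `affinity_fold_change`, `conditional_class`,
#'   `functional_class`, `annotation`, `known_partner`.
#' @export
integrate_evidence <- function(y2h = NULL, coip = NULL, fccs = NULL,
                               dulip = NULL, reporter_classes = NULL,
                               annotations = NULL, threshold = 1.25) {
  y2h_pos <- character(0); profiles <- list()
  if (!is.null(y2h)) {
    stopifnot(inherits(y2h, "y2h_score"))
    profiles <- y2h$domain_profiles
    y2h_pos <- names(profiles)
  }
  norm_df <- function(d) {
    if (is.null(d)) return(NULL)
    d$partner <- .norm_sym(d$partner)
    d
  }
  coip <- norm_df(coip); fccs <- norm_df(fccs); dulip <- norm_df(dulip)
  reporter_classes <- norm_df(reporter_classes)
  annotations <- norm_df(annotations)
  .check_unique(coip, "co-IP"); .check_unique(fccs, "FCCS")
  .check_unique(dulip, "DULIP"); .check_unique(reporter_classes, "reporter")
  .check_unique(annotations, "annotation")

  partners <- sort(unique(c(y2h_pos, coip$partner, fccs$partner,
                            dulip$partner, reporter_classes$partner,
                            annotations$partner)))
  if (length(partners) == 0) {
    rec <- data.frame(partner = character(0), domains_bound = character(0),
                      y2h_positive = logical(0), coip_confirmed = logical(0),
                      kd_fccs_nM = numeric(0), kd_dulip_wt_nM = numeric(0),
                      kd_dulip_ko_nM = numeric(0),
                      affinity_fold_change = numeric(0),
                      conditional_class = character(0),
                      functional_class = character(0),
                      annotation = character(0), known_partner = logical(0))
    return(structure(rec, class = c("interaction_records", "data.frame")))
  }

  pick <- function(d, col, default = NA) {
    if (is.null(d) || !col %in% names(d)) return(rep(default, length(partners)))
    out <- d[[col]][match(partners, d$partner)]
    out
  }
  kd_wt <- pick(dulip, "scaled_kd_wt_nM", NA_real_)
  kd_ko <- pick(dulip, "scaled_kd_ko_nM", NA_real_)
  fold <- ifelse(is.finite(kd_wt) & is.finite(kd_ko) & kd_wt > 0,
                 kd_ko / kd_wt, NA_real_)
  cond <- rep(NA_character_, length(partners))
  both <- is.finite(fold)
  if (any(both)) {
    cond[both] <- classify_conditional_affinity(kd_wt[both], kd_ko[both],
                                                threshold)
  }
  rec <- data.frame(
    partner = partners,
    domains_bound = vapply(partners, function(p) {
      if (p %in% names(profiles)) paste(profiles[[p]], collapse = ",")
      else NA_character_
    }, character(1)),
    y2h_positive = partners %in% y2h_pos,
    coip_confirmed = pick(coip, "confirmed", NA),
    kd_fccs_nM = pick(fccs, "kd_mean", NA_real_),
    kd_dulip_wt_nM = kd_wt,
    kd_dulip_ko_nM = kd_ko,
    affinity_fold_change = fold,
    conditional_class = cond,
    functional_class = pick(reporter_classes, "class", NA_character_),
    annotation = pick(annotations, "annotation", NA_character_),
    known_partner = pick(annotations, "known_partner", NA),
    row.names = NULL
  )
  structure(rec, class = c("interaction_records", "data.frame"))
}

#' Affinity-based edge weights for the binary interaction network
#'
#' Per assay platform, available dissociation constants are log10-min-max
#' normalised to `[0, 1]` across partners; a partner's edge weight is the
#' mean of its available normalised values. Low weight means strong
#' binding (short edge in a weighted layout). If all values on a platform
#' coincide (including a single measured partner) the convention weight
#' 0.5 is assigned and the edge is flagged degenerate.
#'
#' @param records An [integrate_evidence()] result. FCCS uses
#'   `kd_fccs_nM`; DULIP uses `kd_dulip_wt_nM`.
#' @param hub Name of the hub node every partner connects to.
#' @return Data frame of edges: `from`, `to`, `weight`, `evidence`
#'   (comma-joined platforms), `degenerate`. Partners without any
#'   dissociation constant are omitted.
#' @export
compute_edge_weights <- function(records, hub = "NRF2") {
  stopifnot(inherits(records, "interaction_records"))
  norm01 <- function(v) {
    ok <- is.finite(v) & v > 0
    out <- rep(NA_real_, length(v))
    if (!any(ok)) return(list(w = out, degenerate = logical(length(v))))
    lv <- log10(v[ok])
    rng <- range(lv)
    if (diff(rng) == 0) {
      out[ok] <- 0.5
      return(list(w = out, degenerate = ok))
    }
    out[ok] <- (lv - rng[1]) / diff(rng)
    list(w = out, degenerate = rep(FALSE, length(v)))
  }
  f <- norm01(records$kd_fccs_nM)
  d <- norm01(records$kd_dulip_wt_nM)
  has <- is.finite(f$w) | is.finite(d$w)
  if (!any(has)) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), evidence = character(0),
                      degenerate = logical(0)))
  }
  w <- rowMeans(cbind(f$w, d$w), na.rm = TRUE)
  data.frame(
    from = hub,
    to = records$partner[has],
    weight = w[has],
    evidence = vapply(which(has), function(i) {
      paste(c(if (is.finite(f$w[i])) "FCCS", if (is.finite(d$w[i])) "DULIP"),
            collapse = ",")
    }, character(1)),
    degenerate = (f$degenerate | d$degenerate)[has],
    row.names = NULL
  )
}

#' Summarise an integrated interaction-record set
#'
#' Counts records by evidence layer, conditional class and functional
#' class, with percentages reported alongside their numerators and
#' denominators.
#'
#' @param records An [integrate_evidence()] result.
#' @return Object of class `network_summary` (a list of counts and
#'   percentage entries) with a print method.
#' @export
summarise_network <- function(records) {
  stopifnot(inherits(records, "interaction_records"))
  n <- nrow(records)
  pct <- function(num, den) {
    list(numerator = num, denominator = den,
         percent = if (den > 0) 100 * num / den else NA_real_)
  }
  coip_tested <- sum(!is.na(records$coip_confirmed))
  out <- list(
    n_partners = n,
    n_y2h_positive = sum(records$y2h_positive, na.rm = TRUE),
    coip_confirmed = pct(sum(records$coip_confirmed %in% TRUE), coip_tested),
    n_with_fccs_kd = sum(is.finite(records$kd_fccs_nM)),
    n_with_dulip_kd = sum(is.finite(records$kd_dulip_wt_nM)),
    conditional = list(
      gain = sum(records$conditional_class %in% "gain"),
      loss = sum(records$conditional_class %in% "loss"),
      unchanged = sum(records$conditional_class %in% "unchanged")
    ),
    n_conditional_partners = sum(records$conditional_class %in%
                                   c("gain", "loss")),
    functional_class = if (n > 0) {
      as.list(table(unlist(strsplit(
        records$functional_class[!is.na(records$functional_class)], "+",
        fixed = TRUE))))
    } else list(),
    annotation = if (n > 0) {
      as.list(table(records$annotation[!is.na(records$annotation)]))
    } else list()
  )
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("interaction network summary\n")
  cat(sprintf("  partners: %d (Y2H-positive %d, FCCS Kd %d, DULIP Kd %d)\n",
              x$n_partners, x$n_y2h_positive, x$n_with_fccs_kd,
              x$n_with_dulip_kd))
  cc <- x$coip_confirmed
  if (cc$denominator > 0) {
    cat(sprintf("  co-IP confirmed: %d/%d (%.1f%%)\n",
                cc$numerator, cc$denominator, cc$percent))
  }
  cat(sprintf("  conditional affinity: %d loss + %d gain (= %d conditional), %d unchanged\n",
              x$conditional$loss, x$conditional$gain,
              x$n_conditional_partners, x$conditional$unchanged))
  invisible(x)
}
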