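#' Classify a partner's effect on ARE transactivation
#'
#' Applies a declared rule set to the partner's Bonferroni-adjusted
#' contrast table:
#' \itemize{
#'   \item significant WT effect: `activator` if positive, `inhibitor` if
#'     negative;
#'   \item significant dampening (interaction of sign opposite to the WT
#'     effect) in \emph{both} NRF2-null lines: `NRF2_dependent`;
#'   \item no significant WT effect but a significant effect in at least
#'     one derepressed line (KEAP1-null or KEAP1-binding-impaired NRF2):
#'     `derepression_dependent`;
#'   \item otherwise `no_effect`.
#' }
#' Classes other than `no_effect` are not mutually exclusive; a partner can
#' carry several labels. The classification is a pure function of the
#' contrast table.
#'
#' @param contrasts Data frame with columns `cell_line` (`"WT"` for the
#'   baseline effect, otherwise the interaction's cell line), `estimate`,
#'   and `p_adj`.
#' @param alpha Significance level on adjusted p-values.
#' @param null_lines Cell lines lacking NRF2.
#' @param derepressed_lines Cell lines with derepressed NRF2.
#' @param partner Optional partner label carried through.
#' @return Object of class `partner_classification`: `partner`, `classes`
#'   (character vector), `supporting` (the rows that triggered each
#'   label).
#' @export
classify_partner_effect <- function(contrasts, alpha = 0.05,
                                    null_lines = c("NRF2_KO_1", "NRF2_KO_2"),
                                    derepressed_lines = c("NRF2_T80K_T80K",
                                                          "NRF2_T80K_null",
                                                          "KEAP1_KO"),
                                    partner = NA_character_) {
  stopifnot(is.data.frame(contrasts),
            all(c("cell_line", "estimate", "p_adj") %in% names(contrasts)))
  wt <- contrasts[contrasts$cell_line == "WT", , drop = FALSE]
  if (nrow(wt) != 1) {
    return(structure(list(partner = partner, classes = "insufficient_data",
                          supporting = contrasts),
                     class = "partner_classification"))
  }
  sig <- function(rows) rows$p_adj < alpha
  classes <- character(0)
  supporting <- contrasts[0, ]

  wt_sig <- sig(wt)
  if (wt_sig) {
    classes <- c(classes, if (wt$estimate > 0) "activator" else "inhibitor")
    supporting <- rbind(supporting, wt)
  }

  nulls <- contrasts[contrasts$cell_line %in% null_lines, , drop = FALSE]
  if (wt_sig && nrow(nulls) >= length(null_lines)) {
    dampened <- sig(nulls) & sign(nulls$estimate) == -sign(wt$estimate)
    if (all(null_lines %in% nulls$cell_line[dampened])) {
      classes <- c(classes, "NRF2_dependent")
      supporting <- rbind(supporting, nulls[dampened, ])
    }
  }

  derep <- contrasts[contrasts$cell_line %in% derepressed_lines, , drop = FALSE]
  if (!wt_sig && nrow(derep) > 0 && any(sig(derep))) {
    classes <- c(classes, "derepression_dependent")
    supporting <- rbind(supporting, derep[sig(derep), ])
  }

  if (length(classes) == 0) classes <- "no_effect"
  structure(list(partner = partner, classes = classes,
                 supporting = supporting),
            class = "partner_classification")
}

#' @export
print.partner_classification <- function(x, ...) {
  cat(sprintf("partner %s: %s\n",
              if (is.na(x$partner)) "(unnamed)" else x$partner,
              paste(x$classes, collapse = " + ")))
  invisible(x)
}
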