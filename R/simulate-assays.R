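#' Simulate a DULIP saturation series
#'
#' Generates wells of a dual-luminescence co-IP experiment at a known true
#' dissociation constant: the Renilla-tagged bait is held at a fixed total
#' while the firefly-tagged prey spans a log-spaced saturation series.
#' Input luminescences are proportional to total tagged protein; bound
#' luminescences are proportional to captured bait and to the equilibrium
#' complex; each luminescence carries multiplicative log-normal well noise.
#'
#' @param kd_true True dissociation constant (nM).
#' @param n_wells Number of wells (>= 1).
#' @param bait_nM Total bait concentration (nM).
#' @param prey_range_nM Length-2 range of total prey concentration (nM);
#'   wells are log-spaced across it.
#' @param gain_fl,gain_rl Luminescence per nM for firefly and Renilla.
#' @param capture Fraction of bait (and its bound prey) captured on the
#'   plate.
#' @param background Additive background luminescence on bound firefly.
#' @param noise_sd Standard deviation of the log-normal well noise (on the
#'   natural-log scale); 0 gives deterministic wells.
#' @param cell_line,condition,experiment Labels copied onto every well.
#' @param seed Integer seed.
#' @return Data frame of wells: `pair_id`, `fl_input`, `rl_input`,
#'   `fl_bound`, `rl_bound`, `replicate`, `experiment`, `cell_line`,
#'   `condition`, plus the ground-truth columns `prey_total_nM` and
#'   `complex_nM`.
#' @export
simulate_dulip_assay <- function(kd_true, n_wells = 12, bait_nM = 100,
                                 prey_range_nM = c(kd_true / 10, kd_true * 20),
                                 gain_fl = 1, gain_rl = 1, capture = 1,
                                 background = 0, noise_sd = 0.1,
                                 cell_line = "WT", condition = "wt_bait",
                                 experiment = 1L, seed = 1L) {
  if (n_wells < 1) stop("simulate_dulip_assay: n_wells must be >= 1")
  if (kd_true < 0 || noise_sd < 0) {
    stop("simulate_dulip_assay: kd_true and noise_sd must be >= 0")
  }
  set.seed(seed)
  prey <- 10^seq(log10(prey_range_nM[1]), log10(prey_range_nM[2]),
                 length.out = n_wells)
  lnoise <- function() exp(stats::rnorm(n_wells, 0, noise_sd))
  complex_nM <- vapply(prey, function(p) {
    solve_equilibrium(bait_nM, p, kd_true)$c_complex
  }, numeric(1))
  data.frame(
    pair_id = sprintf("well_%02d", seq_len(n_wells)),
    fl_input = gain_fl * prey * lnoise(),
    rl_input = gain_rl * bait_nM * lnoise(),
    fl_bound = gain_fl * capture * complex_nM * lnoise() + background,
    rl_bound = gain_rl * capture * bait_nM * lnoise(),
    replicate = seq_len(n_wells),
    experiment = experiment,
    cell_line = cell_line,
    condition = condition,
    prey_total_nM = prey,
    complex_nM = complex_nM
  )
}

#' Simulate an ARE-reporter screen with plate structure
#'
#' Generates one well per plate x cell-line x condition x replicate of a
#' dual-luciferase reporter screen. The log2 firefly/Renilla ratio of a
#' well is
#' `intercept + condition effect + cell-line effect + interaction +
#' plate intercept + residual`, with the plate intercept drawn from
#' `N(0, sigma_plate^2)` and the residual from `N(0, sigma_resid^2)`.
#' The reference condition `empty_vector` and reference cell line (first of
#' `cell_lines`) have zero effects. Raw luminescences consistent with the
#' ratio are emitted so the normalisation step can be exercised too.
#'
#' @param condition_effects Named numeric vector of condition (partner)
#'   effects on the log2 scale; names become the non-reference conditions.
#' @param cell_line_effects Named numeric vector of cell-line effects; the
#'   reference cell line `WT` is prepended with effect 0.
#' @param interaction_effects Optional matrix of condition x cell-line
#'   interaction effects (rownames = conditions, colnames = non-reference
#'   cell lines); defaults to zero.
#' @param intercept Baseline log2 ratio.
#' @param sigma_plate,sigma_resid Standard deviations (>= 0) of the plate
#'   random intercept and the residual.
#' @param n_plates,replicates Plates and within-plate replicates.
#' @param rl_base Renilla luminescence of every well (sets the raw scale).
#' @param seed Integer seed.
#' @return Data frame of observations: `plate`, `cell_line`, `condition`,
#'   `replicate`, `fl`, `rl`, `log2_ratio`.
#' @export
simulate_reporter_study <- function(condition_effects = c(partner = 1),
                                    cell_line_effects = numeric(0),
                                    interaction_effects = NULL,
                                    intercept = 0,
                                    sigma_plate = 0.3, sigma_resid = 0.5,
                                    n_plates = 6, replicates = 3,
                                    rl_base = 1000, seed = 1L) {
  if (sigma_plate < 0 || sigma_resid < 0) {
    stop("simulate_reporter_study: variances must be >= 0")
  }
  set.seed(seed)
  conditions <- c("empty_vector", names(condition_effects))
  cell_lines <- c("WT", names(cell_line_effects))
  cond_eff <- c(empty_vector = 0, condition_effects)
  cl_eff <- c(WT = 0, cell_line_effects)
  inter <- matrix(0, length(conditions), length(cell_lines),
                  dimnames = list(conditions, cell_lines))
  if (!is.null(interaction_effects)) {
    inter[rownames(interaction_effects), colnames(interaction_effects)] <-
      interaction_effects
  }
  plate_int <- stats::rnorm(n_plates, 0, sigma_plate)
  d <- expand.grid(replicate = seq_len(replicates),
                   condition = conditions, cell_line = cell_lines,
                   plate = seq_len(n_plates),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- intercept + cond_eff[d$condition] + cl_eff[d$cell_line] +
    inter[cbind(d$condition, d$cell_line)] + plate_int[d$plate]
  d$log2_ratio <- unname(mu + stats::rnorm(nrow(d), 0, sigma_resid))
  d$rl <- rl_base
  d$fl <- rl_base * 2^d$log2_ratio
  d$plate <- factor(d$plate)
  d$condition <- factor(d$condition, levels = conditions)
  d$cell_line <- factor(d$cell_line, levels = cell_lines)
  d[c("plate", "cell_line", "condition", "replicate", "fl", "rl",
      "log2_ratio")]
}

#' Simulate a yeast two-hybrid matrix screen
#'
#' Every tested bait-prey pair is assayed in two independent replicates,
#' each read out on the ADE2 and HIS3 growth reporters. A true edge
#' produces growth in a replicate with probability `p_repro`
#' (independently per replicate); a non-edge produces growth with the
#' false-positive probability `p_false`. Auto-activating clones grow
#' regardless of interaction and are flagged.
#'
#' @param pairs Data frame of tested pairs with columns `bait`, `prey` and
#'   optionally `nrf2_fragment` (default `"FL"`).
#' @param true_edges Data frame (columns `bait`, `prey`, optional
#'   `nrf2_fragment`) of genuinely interacting pairs.
#' @param p_repro Per-replicate growth probability of a true edge.
#' @param p_false Per-replicate growth probability of a non-edge.
#' @param autoactivators Character vector of auto-activating prey clones.
#' @param n_replicates Independent assay replicates per pair (>= 2 for the
#'   scoring rule to apply).
#' @param seed Integer seed.
#' @return Data frame of calls: `bait`, `prey`, `nrf2_fragment`,
#'   `assay_replicate`, `reporter`, `growth`, `autoactivator`.
#' @export
simulate_y2h_screen <- function(pairs, true_edges, p_repro = 1,
                                p_false = 0, autoactivators = character(0),
                                n_replicates = 2, seed = 1L) {
  stopifnot(is.data.frame(pairs), all(c("bait", "prey") %in% names(pairs)))
  if (p_repro < 0 || p_repro > 1 || p_false < 0 || p_false > 1) {
    stop("simulate_y2h_screen: probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  if (is.null(pairs$nrf2_fragment)) pairs$nrf2_fragment <- "FL"
  if (!is.null(true_edges) && is.null(true_edges$nrf2_fragment)) {
    true_edges$nrf2_fragment <- "FL"
  }
  key <- function(d) paste(d$bait, d$prey, d$nrf2_fragment, sep = "\r")
  is_true <- key(pairs) %in% if (is.null(true_edges)) character(0) else key(true_edges)
  is_auto <- pairs$prey %in% autoactivators

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p_grow <- if (is_auto[i]) 1 else if (is_true[i]) p_repro else p_false
    grow_rep <- stats::runif(n_replicates) < p_grow
    rows[[i]] <- data.frame(
      bait = pairs$bait[i], prey = pairs$prey[i],
      nrf2_fragment = pairs$nrf2_fragment[i],
      assay_replicate = rep(seq_len(n_replicates), each = 2),
      reporter = rep(c("ADE2", "HIS3"), n_replicates),
      growth = rep(grow_rep, each = 2),
      autoactivator = is_auto[i]
    )
  }
  do.call(rbind, rows)
}
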