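call_row <- function(prey, rep, reporter, growth, auto = FALSE,
                     frag = "FL") {
  data.frame(bait = "NRF2", prey = prey, nrf2_fragment = frag,
             assay_replicate = rep, reporter = reporter, growth = growth,
             autoactivator = auto)
}

test_that("the reproducible-in-two scoring rule is applied exactly", {
  calls <- rbind(
    call_row("A", 1, "ADE2", TRUE), call_row("A", 2, "HIS3", TRUE),
    call_row("B", 1, "ADE2", TRUE), call_row("B", 2, "ADE2", FALSE),
    call_row("C", 1, "ADE2", TRUE), call_row("C", 2, "HIS3", TRUE,
                                             auto = TRUE),
    call_row("D", 1, "ADE2", TRUE))
  sc <- score_y2h_matrix(calls)
  status <- setNames(sc$pairs$status, sc$pairs$prey)
  expect_identical(status[["A"]], "positive")
  expect_identical(status[["B"]], "negative")
  expect_identical(status[["C"]], "excluded_autoactivator")
  expect_identical(status[["D"]], "untested_incomplete")
  expect_identical(sc$domain_profiles, list(A = "FL"))
})

test_that("either reporter counts as growth within a replicate", {
  calls <- rbind(
    call_row("A", 1, "ADE2", FALSE), call_row("A", 1, "HIS3", TRUE),
    call_row("A", 2, "ADE2", TRUE), call_row("A", 2, "HIS3", FALSE))
  expect_identical(score_y2h_matrix(calls)$pairs$status, "positive")
})

test_that("scoring is monotone: extra growth never removes a positive", {
  base <- rbind(
    call_row("A", 1, "ADE2", TRUE), call_row("A", 2, "ADE2", TRUE))
  expect_identical(score_y2h_matrix(base)$pairs$status, "positive")
  more <- rbind(base, call_row("A", 3, "HIS3", TRUE))
  expect_identical(score_y2h_matrix(more)$pairs$status, "positive")
})

test_that("domain profiles collect positive fragments per partner", {
  calls <- rbind(
    call_row("NRF2-Neh2", 1, "ADE2", TRUE, frag = "Neh2"),
    call_row("NRF2-Neh2", 2, "HIS3", TRUE, frag = "Neh2"),
    call_row("NRF2-FL", 1, "ADE2", TRUE, frag = "FL"),
    call_row("NRF2-FL", 2, "ADE2", TRUE, frag = "FL"))
  calls$prey <- "keap1"
  sc <- score_y2h_matrix(calls)
  expect_identical(sc$domain_profiles$KEAP1, c("FL", "Neh2"))
})

test_that("partial reproducibility yields roughly p-squared positives", {
  set.seed(91)
  pairs <- data.frame(bait = "NRF2", prey = sprintf("P%04d", 1:1000))
  calls <- simulate_y2h_screen(pairs, pairs, p_repro = 0.7, seed = 91)
  sc <- score_y2h_matrix(calls)
  rate <- mean(sc$pairs$status == "positive")
  p2 <- 0.7^2
  expect_lt(abs(rate - p2), 3 * sqrt(p2 * (1 - p2) / 1000))
})

test_that("conditional affinity classification honours the strict threshold", {
  expect_identical(classify_conditional_affinity(1000, 2000), "loss")
  expect_identical(classify_conditional_affinity(2000, 1000), "gain")
  expect_identical(classify_conditional_affinity(1000, 1000), "unchanged")
  expect_identical(classify_conditional_affinity(1000, 1250), "unchanged")
  expect_identical(classify_conditional_affinity(1250, 1000), "unchanged")
  expect_identical(classify_conditional_affinity(1000, 1250.001), "loss")
  expect_error(classify_conditional_affinity(0, 100), "> 0")
})

test_that("conditional classes invert when the cell lines are swapped", {
  set.seed(93)
  inverse <- c(gain = "loss", loss = "gain", unchanged = "unchanged")
  for (i in 1:50) {
    a <- 10^runif(1, 1, 4); b <- 10^runif(1, 1, 4)
    expect_identical(classify_conditional_affinity(b, a),
                     unname(inverse[classify_conditional_affinity(a, b)]))
  }
})

test_that("evidence integration joins layers and counts confirmations", {
  empty <- integrate_evidence()
  expect_identical(nrow(empty), 0L)
  expect_identical(summarise_network(empty)$n_partners, 0L)

  partners <- sprintf("G%02d", 1:43)
  coip <- data.frame(partner = partners,
                     confirmed = rep(c(TRUE, FALSE), c(27, 16)))
  rec <- integrate_evidence(coip = coip)
  s <- summarise_network(rec)
  expect_identical(s$coip_confirmed$numerator, 27L)
  expect_identical(s$coip_confirmed$denominator, 43L)
  expect_equal(s$coip_confirmed$percent, 100 * 27 / 43, tolerance = 1e-10)

  # partner present only in Y2H: quantitative fields explicitly absent
  calls <- rbind(call_row("A", 1, "ADE2", TRUE), call_row("A", 2, "HIS3", TRUE))
  rec2 <- integrate_evidence(y2h = score_y2h_matrix(calls))
  expect_true(rec2$y2h_positive[rec2$partner == "A"])
  expect_true(is.na(rec2$kd_fccs_nM[rec2$partner == "A"]))
  expect_true(is.na(rec2$conditional_class[rec2$partner == "A"]))

  dup <- data.frame(partner = c("A", "a"), confirmed = c(TRUE, FALSE))
  expect_error(integrate_evidence(coip = dup), "conflicting duplicate")
})

test_that("conditional classes flow from the paired DULIP constants", {
  dulip <- data.frame(partner = c("L1", "G1", "U1"),
                      scaled_kd_wt_nM = c(1000, 2000, 1000),
                      scaled_kd_ko_nM = c(2000, 1000, 1100))
  rec <- integrate_evidence(dulip = dulip)
  cls <- setNames(rec$conditional_class, rec$partner)
  expect_identical(cls[["L1"]], "loss")
  expect_identical(cls[["G1"]], "gain")
  expect_identical(cls[["U1"]], "unchanged")
  s <- summarise_network(rec)
  expect_identical(s$n_conditional_partners, 2L)
})

test_that("summary counts loss and gain partners like the study reports", {
  n <- 20
  kd_wt <- rep(1000, n)
  kd_ko <- c(rep(2000, 7), rep(500, 6), rep(1000, 7))
  dulip <- data.frame(partner = sprintf("P%02d", 1:n),
                      scaled_kd_wt_nM = kd_wt, scaled_kd_ko_nM = kd_ko)
  s <- summarise_network(integrate_evidence(dulip = dulip))
  expect_identical(s$conditional$loss, 7L)
  expect_identical(s$conditional$gain, 6L)
  expect_identical(s$n_conditional_partners, 13L)
  expect_identical(s$conditional$unchanged, 7L)
})

test_that("edge weights are log10 min-max normalised means", {
  fccs <- data.frame(partner = c("A", "B", "C"),
                     kd_mean = c(100, 1000, 10000))
  rec <- integrate_evidence(fccs = fccs)
  e <- compute_edge_weights(rec)
  w <- setNames(e$weight, e$to)
  expect_equal(unname(w[c("A", "B", "C")]), c(0, 0.5, 1), tolerance = 1e-12)
  expect_true(all(e$weight >= 0 & e$weight <= 1))
  expect_false(any(e$degenerate))

  # partner strongest on both platforms sits at weight 0
  dulip <- data.frame(partner = c("A", "B", "C"),
                      scaled_kd_wt_nM = c(50, 2000, 8000),
                      scaled_kd_ko_nM = NA_real_)
  rec2 <- integrate_evidence(fccs = fccs, dulip = dulip)
  e2 <- compute_edge_weights(rec2)
  expect_equal(e2$weight[e2$to == "A"], 0, tolerance = 1e-12)

  # single measured partner: degenerate convention 0.5
  single <- integrate_evidence(fccs = data.frame(partner = "X",
                                                 kd_mean = 500))
  es <- compute_edge_weights(single)
  expect_equal(es$weight, 0.5)
  expect_true(es$degenerate)

  # weight order follows Kd order within a platform
  set.seed(97)
  kds <- 10^runif(8, 1, 4)
  recw <- integrate_evidence(fccs = data.frame(partner = sprintf("W%d", 1:8),
                                               kd_mean = kds))
  ew <- compute_edge_weights(recw)
  expect_identical(order(ew$weight), order(kds))
})
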