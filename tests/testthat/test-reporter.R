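test_that("luciferase normalisation reproduces hand-computed fold changes", {
  obs <- data.frame(
    plate = 1, cell_line = "WT",
    condition = c("empty_vector", "empty_vector", "p1", "p1", "p2", "p2"),
    fl = c(100, 400, 400, 800, 100, 50),
    rl = c(100, 100, 100, 100, 100, 100))
  out <- normalise_luciferase(obs)
  base <- sqrt(1 * 4)  # geometric mean of baseline ratios 1 and 4
  expect_equal(out$log2_fc,
               log2(c(1, 4, 4, 8, 1, 0.5) / base), tolerance = 1e-12)
  # a well identical to the baseline mean has fold change zero
  expect_equal(out$log2_fc[1] + out$log2_fc[2], 0, tolerance = 1e-12)
})

test_that("plates without a baseline are excluded with a warning", {
  obs <- data.frame(
    plate = c(1, 1, 2, 2), cell_line = "WT",
    condition = c("empty_vector", "p1", "p1", "p1"),
    fl = c(100, 200, 100, 120), rl = 100)
  expect_warning(out <- normalise_luciferase(obs), "plate")
  expect_identical(unique(out$plate), 1)
  expect_error(normalise_luciferase(transform(obs, fl = -fl)), "> 0")
})

test_that("with no plate variance the LMM equals ordinary least squares", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 0.6),
                               cell_line_effects = c(KO = 0.4),
                               sigma_plate = 0, sigma_resid = 0.3,
                               n_plates = 4, replicates = 3, seed = 13)
  f <- fit_reporter_lmm(d, log2_ratio ~ condition * cell_line)
  ols <- lm(log2_ratio ~ condition * cell_line, d)
  # balanced design: GLS coincides with OLS whatever the variance ratio
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("a known condition effect is recovered within 3 SE", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 1.0),
                               sigma_plate = 0.3, sigma_resid = 0.5,
                               n_plates = 6, replicates = 3, seed = 17)
  f <- fit_reporter_lmm(d, log2_ratio ~ condition)
  sw <- satterthwaite_contrast(f, "conditionp1")
  expect_lt(abs(sw$estimate - 1.0), 3 * sw$se)
})

test_that("the fit is invariant to row order", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 0.5),
                               sigma_plate = 0.2, sigma_resid = 0.4,
                               n_plates = 5, replicates = 2, seed = 19)
  f1 <- fit_reporter_lmm(d, log2_ratio ~ condition)
  set.seed(1)
  f2 <- fit_reporter_lmm(d[sample(nrow(d)), ], log2_ratio ~ condition)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-10)
})

test_that("rank-deficient designs raise an explicit aliasing error", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 0.5),
                               sigma_plate = 0.2, sigma_resid = 0.4,
                               n_plates = 3, replicates = 2, seed = 23)
  d$dup <- as.numeric(d$condition == "p1")
  expect_error(fit_reporter_lmm(d, log2_ratio ~ condition + dup),
               "aliased")
})

test_that("fixed effects and REML likelihood match the reference mixed-model fitter", {
  skip_if_not_installed("lmerTest")
  set.seed(29)
  for (i in 1:6) {
    d <- simulate_reporter_study(
      condition_effects = c(p1 = runif(1, -1, 1)),
      cell_line_effects = c(KO = runif(1, -1, 1)),
      sigma_plate = runif(1, 0.05, 0.5), sigma_resid = runif(1, 0.2, 0.7),
      n_plates = sample(4:8, 1), replicates = sample(2:4, 1),
      seed = 100 + i)
    f <- fit_reporter_lmm(d, log2_ratio ~ condition * cell_line)
    m <- lmerTest::lmer(log2_ratio ~ condition * cell_line + (1 | plate),
                        d, REML = TRUE)
    expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-4)
    expect_equal(f$reml_loglik, as.numeric(logLik(m)), tolerance = 1e-4)
    sw <- satterthwaite_contrast(f, "conditionp1")
    ref <- summary(m)$coefficients["conditionp1", ]
    expect_equal(sw$df, unname(ref["df"]), tolerance = 1e-2)
    expect_equal(sw$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-4)
  }
})

test_that("Satterthwaite df reduces to the classical residual df at the boundary", {
  # identical within-plate patterns: between-plate variance is below the
  # within-plate variance, so the REML plate variance hits the zero boundary
  pattern <- c(0.10, -0.20, 0.05, 1.10, 0.90, 1.05)
  d <- data.frame(
    plate = rep(1:4, each = 6),
    condition = rep(rep(c("empty_vector", "p1"), each = 3), 4),
    log2_ratio = rep(pattern, 4))
  f <- fit_reporter_lmm(d, log2_ratio ~ condition)
  expect_identical(f$sigma_plate2, 0)
  sw <- satterthwaite_contrast(f, "conditionp1")
  expect_equal(sw$df, f$n - f$p)
})

test_that("contrast tests are scale invariant", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 0.7),
                               sigma_plate = 0.3, sigma_resid = 0.5,
                               n_plates = 6, replicates = 3, seed = 37)
  f1 <- fit_reporter_lmm(d, log2_ratio ~ condition)
  d10 <- d; d10$log2_ratio <- d10$log2_ratio * 10
  f2 <- fit_reporter_lmm(d10, log2_ratio ~ condition)
  s1 <- satterthwaite_contrast(f1, "conditionp1")
  s2 <- satterthwaite_contrast(f2, "conditionp1")
  expect_equal(s1$t, s2$t, tolerance = 1e-6)
  expect_equal(s1$df, s2$df, tolerance = 1e-4)
  expect_equal(s1$p, s2$p, tolerance = 1e-6)
  expect_error(satterthwaite_contrast(f1, c(0, 0)), "zero contrast")
})

test_that("Bonferroni adjustment clamps, preserves order and validates", {
  expect_equal(adjust_bonferroni(0.01, m = 5), 0.05)
  expect_equal(adjust_bonferroni(0.5, m = 3), 1)
  p <- sort(runif(10))
  expect_true(!is.unsorted(adjust_bonferroni(p)))
  expect_equal(adjust_bonferroni(p), pmin(1, 10 * p))
  expect_error(adjust_bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("partner classification follows the declared rule set", {
  mk <- function(...) {
    d <- data.frame(...)
    names(d) <- c("cell_line", "estimate", "p_adj")
    d
  }
  lines <- c("WT", "NRF2_KO_1", "NRF2_KO_2", "NRF2_T80K_T80K",
             "NRF2_T80K_null", "KEAP1_KO")

  all_null <- mk(lines, rep(0.1, 6), rep(1, 6))
  expect_identical(classify_partner_effect(all_null)$classes, "no_effect")

  act <- mk(lines, c(1, 0, 0, 0, 0, 0), c(0.001, 1, 1, 1, 1, 1))
  expect_identical(classify_partner_effect(act)$classes, "activator")

  inh <- mk(lines, c(-1.2, 0, 0, 0, 0, 0), c(0.001, 1, 1, 1, 1, 1))
  expect_identical(classify_partner_effect(inh)$classes, "inhibitor")

  derep <- mk(lines, c(0, 0, 0, 0, 0, 1), c(0.9, 1, 1, 1, 1, 0.01))
  expect_identical(classify_partner_effect(derep)$classes,
                   "derepression_dependent")

  dep <- mk(lines, c(1, -0.8, -0.9, 0, 0, 0),
            c(0.001, 0.01, 0.02, 1, 1, 1))
  expect_setequal(classify_partner_effect(dep)$classes,
                  c("activator", "NRF2_dependent"))

  # dampening in only one null line is not NRF2-dependence
  half <- mk(lines, c(1, -0.8, 0, 0, 0, 0), c(0.001, 0.01, 1, 1, 1, 1))
  expect_identical(classify_partner_effect(half)$classes, "activator")

  incomplete <- mk("NRF2_KO_1", 0.5, 0.01)
  expect_identical(classify_partner_effect(incomplete)$classes,
                   "insufficient_data")
})
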