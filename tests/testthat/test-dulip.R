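test_that("NIR arithmetic, linearity and scale invariance", {
  expect_equal(compute_nir(100, 100, 200, 50), 4)
  expect_equal(compute_nir(100, 100, 400, 50), 8)  # doubling bound FL
  w <- data.frame(fl_input = 120, rl_input = 80, fl_bound = 30, rl_bound = 60)
  expect_equal(compute_nir(w), compute_nir(w * 7))  # whole-well gain
  # bound ratio equal to input ratio: no enrichment
  expect_equal(compute_nir(50, 25, 100, 50), 1)
  expect_warning(out <- compute_nir(0, 10, 5, 5), "excluded")
  expect_true(is.na(out))
})

test_that("cNIR is NIR relative to the negative control", {
  expect_equal(compute_cnir(4, 2), 2)
  expect_equal(compute_cnir(3, 3), 1)
  expect_equal(compute_cnir(2.5, 1), 2.5)
  expect_warning(out <- compute_cnir(4, 0), "control")
  expect_true(is.na(out))
})

test_that("noise-free saturation series recovers the generating Kd exactly", {
  w <- simulate_dulip_assay(kd_true = 500, n_wells = 12, bait_nM = 100,
                            noise_sd = 0, seed = 1)
  est <- estimate_dulip_kd(w)
  expect_false(est$sentinel)
  expect_equal(est$kd_dulip, 500, tolerance = 1e-6)
})

test_that("background-only wells give the unbounded-K sentinel", {
  w <- simulate_dulip_assay(kd_true = 1e12, n_wells = 10, bait_nM = 100,
                            prey_range_nM = c(50, 5000), background = 0.2,
                            noise_sd = 0, seed = 1)
  est <- estimate_dulip_kd(w)
  expect_true(est$sentinel)
  expect_identical(est$kd_dulip, Inf)
})

test_that("noisy saturation series recovers Kd within 20%", {
  w <- simulate_dulip_assay(kd_true = 800, n_wells = 16, bait_nM = 100,
                            noise_sd = 0.1, seed = 4)
  est <- estimate_dulip_kd(w)
  expect_lt(abs(est$kd_dulip - 800) / 800, 0.2)
  expect_true(is.finite(est$sem) && est$sem > 0)
})

test_that("the Kd estimate is invariant to the Renilla/capture gain", {
  w <- simulate_dulip_assay(kd_true = 300, n_wells = 12, noise_sd = 0.05,
                            seed = 6)
  est1 <- estimate_dulip_kd(w)
  w2 <- w
  w2$rl_input <- w$rl_input * 2
  w2$rl_bound <- w$rl_bound * 2
  est2 <- estimate_dulip_kd(w2)
  expect_equal(est1$kd_dulip, est2$kd_dulip, tolerance = 1e-6)
  # equivalently through the alpha argument
  est3 <- estimate_dulip_kd(w, alpha = 2)
  expect_equal(est1$kd_dulip, est3$kd_dulip, tolerance = 1e-6)
})

test_that("mutant-effect t-test matches the textbook formula", {
  null_res <- test_mutant_effect(c(1, 1, 1))
  expect_identical(null_res$t, 0)
  expect_identical(null_res$p, 1)
  expect_true(null_res$degenerate)

  deg <- test_mutant_effect(2^c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_identical(deg$p, 0)

  x <- c(0.8, 1.1, 1.3)
  res <- test_mutant_effect(2^x)
  expect_equal(res$t, mean(x) / (sd(x) / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(res$t), 2), tolerance = 1e-12)

  # sign flip: reciprocal ratios flip t, keep p
  res_inv <- test_mutant_effect(2^(-x))
  expect_equal(res_inv$t, -res$t, tolerance = 1e-12)
  expect_equal(res_inv$p, res$p, tolerance = 1e-12)
})

test_that("triplicates are averaged within experiment before testing", {
  d <- data.frame(experiment = rep(1:3, each = 3),
                  cnir = 2^c(0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.2, 1.3, 1.4))
  res <- test_mutant_effect(d)
  expect_identical(res$n, 3L)
  expect_equal(res$mean_log2, mean(c(0.8, 1.1, 1.3)), tolerance = 1e-12)
})
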