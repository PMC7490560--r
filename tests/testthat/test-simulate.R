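test_that("zero-noise simulated curves equal the analytic models exactly", {
  cfg <- fccs_sim_config(n_cells = 1, kd_true = 800, noise_sd_scale = 0,
                         seed = 5)
  mp <- fccs_model_params()
  st <- solve_equilibrium(900, 1100, 800)
  cur <- simulate_fccs_curves(st, cfg, mp)

  n_g <- st$c_g_total * 1e-9 * 6.02214076e23 * cfg$volume$v_eff * 1e-15
  pg <- diffusion_params(n_g, f_fast = 1 - st$c_complex / st$c_g_total,
                         tau_d_fast = mp$tau_free_green,
                         tau_d_slow = mp$tau_complex,
                         triplet_fraction = mp$triplet_fraction,
                         tau_triplet = mp$tau_triplet)
  expect_identical(cur$green_auto$g,
                   eval_autocorr_model(cur$green_auto$lags, pg, cfg$volume))
  expect_true(all(cur$green_auto$sem == 0))
  # cross amplitude carries the complex concentration
  n_x <- st$c_complex * 1e-9 * 6.02214076e23 * cfg$volume$v_eff * 1e-15
  n_r <- st$c_r_total * 1e-9 * 6.02214076e23 * cfg$volume$v_eff * 1e-15
  expect_equal(cur$cross$g[1],
               (n_x / (n_g * n_r)) *
                 eval_crosscorr_model(cur$cross$lags[1],
                                      diffusion_params(1, 0, mp$tau_complex,
                                                       mp$tau_complex),
                                      cfg$volume),
               tolerance = 1e-12)
})

test_that("identical seeds reproduce identical populations", {
  cfg <- fccs_sim_config(n_cells = 3, kd_true = 1000, noise_sd_scale = 0.05,
                         seed = 77)
  p1 <- simulate_cell_population(cfg)
  p2 <- simulate_cell_population(cfg)
  expect_identical(p1$cells[[3]]$curves$cross$g, p2$cells[[3]]$curves$cross$g)
  expect_identical(p1$cells[[2]]$truth$c_complex, p2$cells[[2]]$truth$c_complex)
})

test_that("zero expression spread gives identical totals across cells", {
  cfg <- fccs_sim_config(n_cells = 4, expression_log10_sd = c(0, 0),
                         kd_true = 500, noise_sd_scale = 0, seed = 9)
  pop <- simulate_cell_population(cfg)
  totals <- sapply(pop$cells, function(cell) cell$truth$c_g_total)
  expect_true(all(totals == totals[1]))
})

test_that("noisy replicate curves average to the analytic value", {
  cfg <- fccs_sim_config(n_cells = 1, kd_true = 1000, noise_sd_scale = 0.1,
                         seed = 1)
  mp <- fccs_model_params(lags = make_lag_ladder(1e-6, 8, 16))
  st <- solve_equilibrium(1000, 1000, 1000)
  clean <- simulate_fccs_curves(st, fccs_sim_config(noise_sd_scale = 0,
                                                    kd_true = 1000, seed = 1),
                                mp)$green_auto
  set.seed(33)
  reps <- replicate(1000, simulate_fccs_curves(st, cfg, mp,
                                               seed = NULL)$green_auto$g)
  mc_mean <- rowMeans(reps)
  mc_sem <- apply(reps, 1, sd) / sqrt(1000)
  z <- abs(mc_mean - clean$g) / pmax(mc_sem, 1e-300)
  # per-lag 3-sigma agreement; across ~10^2 lags a couple of benign
  # exceedances are expected by chance, none extreme
  expect_gte(mean(z <= 3), 0.97)
  expect_true(all(z <= 5))
})

test_that("photon-trace simulator handles degenerate inputs", {
  vol <- confocal_volume(w0 = 0.2, s = 5)
  empty <- solve_equilibrium(0, 0, 100)
  tr <- simulate_photon_traces(empty, vol, c(green = 25, red = 25, complex = 10),
                               dt = 1e-5, n_steps = 4096, seed = 1)
  expect_true(all(tr$green == 0) && all(tr$red == 0))

  # immobile particles: Poisson counts with a constant mean
  one <- solve_equilibrium(3, 0, 1e9)
  tr2 <- simulate_photon_traces(one, vol, c(green = 0, red = 0, complex = 0),
                                dt = 1e-4, n_steps = 8192, seed = 2,
                                brightness = 5)
  expect_gt(sum(tr2$green >= 0), 0)
  h1 <- mean(tr2$green[1:4096]); h2 <- mean(tr2$green[4097:8192])
  expect_lt(abs(h1 - h2), 5 * sqrt(mean(tr2$green) / 4096) + 1e-9)

  expect_error(simulate_photon_traces(one, vol, c(green = 25, red = 25,
                                                  complex = 10),
                                      dt = 0, n_steps = 100), "dt")
  expect_error(simulate_photon_traces(one, vol, c(green = 25, red = 25,
                                                  complex = 10),
                                      dt = 1e-5, n_steps = 100,
                                      box_factor = 5), "10 beam waists")
})

test_that("dulip simulator limits behave as designed", {
  # essentially no binding: bound firefly is all background
  w <- simulate_dulip_assay(kd_true = 1e12, n_wells = 8, bait_nM = 100,
                            prey_range_nM = c(10, 1000), background = 0.5,
                            noise_sd = 0, seed = 1)
  expect_true(all(abs(w$fl_bound - 0.5) < 1e-6))
  # no noise: NIR identical across wells of identical expression
  w2 <- simulate_dulip_assay(kd_true = 100, n_wells = 2, bait_nM = 50,
                             prey_range_nM = c(200, 200.0001),
                             noise_sd = 0, seed = 1)
  nir <- compute_nir(w2)
  expect_equal(nir[1], nir[2], tolerance = 1e-6)
  expect_error(simulate_dulip_assay(100, n_wells = 0), "n_wells")
})

test_that("reporter simulator is exact in the noise-free limit", {
  d <- simulate_reporter_study(condition_effects = c(p1 = 0),
                               intercept = 0.4, sigma_plate = 0,
                               sigma_resid = 0, n_plates = 2, seed = 1)
  expect_true(all(abs(d$log2_ratio - 0.4) < 1e-12))
  expect_error(simulate_reporter_study(sigma_plate = -1), "variances")
})

test_that("y2h simulator hits the deterministic limits", {
  pairs <- data.frame(bait = "NRF2", prey = c("A", "B", "C"))
  edges <- data.frame(bait = "NRF2", prey = c("A", "C"))
  calls <- simulate_y2h_screen(pairs, edges, p_repro = 1, seed = 1)
  sc <- score_y2h_matrix(calls)
  expect_setequal(sc$pairs$prey[sc$pairs$status == "positive"], c("A", "C"))
  calls0 <- simulate_y2h_screen(pairs, edges, p_repro = 0, seed = 1)
  sc0 <- score_y2h_matrix(calls0)
  expect_identical(sum(sc0$pairs$status == "positive"), 0L)
})
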