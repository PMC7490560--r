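# Independent brute-force correlator: scalar accumulation per lag, no
# shared code with the package implementation.
brute_force_correlate <- function(a, b, lag_samples) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  out <- numeric(length(lag_samples))
  for (j in seq_along(lag_samples)) {
    k <- lag_samples[j]
    acc <- 0
    for (t in seq_len(n - k)) acc <- acc + a[t] * b[t + k]
    out[j] <- (acc / (n - k)) / (ma * mb) - 1
  }
  out
}

test_volume <- function() confocal_volume(v_eff = 0.25, s = 5, w0 = 0.2)

# build a cell_measurement directly from known concentrations (inverse of
# amplitudes_to_concentrations) for fixture construction
measurement_from_concentrations <- function(c_g, c_r, c_complex, volume,
                                            meta = list()) {
  unit <- 1 / (1e-9 * 6.02214076e23 * volume$v_eff * 1e-15)
  g0_g <- unit / c_g
  g0_r <- unit / c_r
  g0_x <- c_complex * g0_g * g0_r / unit
  amplitudes_to_concentrations(g0_g, g0_r, g0_x, volume, meta = meta)
}

# random but identifiable diffusion parameter set for round-trip tests
sample_diffusion_params <- function() {
  tau_fast <- 10^runif(1, -4.3, -3.3)
  diffusion_params(
    n_particles = 10^runif(1, -0.5, 1.5),
    f_fast = runif(1, 0.25, 0.75),
    tau_d_fast = tau_fast,
    tau_d_slow = tau_fast * 10^runif(1, 0.9, 1.6),
    triplet_fraction = runif(1, 0.05, 0.3),
    tau_triplet = 10^runif(1, -5.7, -5),
    offset = runif(1, 5e-4, 3e-3)
  )
}
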