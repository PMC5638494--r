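# Lifetime and anisotropy analysis: exact recovery, averages, identities
# and frequency-domain properties.

test_that("noiseless single-exponential recovery is exact in both domains", {
  sw <- gen_frequency_sweep(decay_model(1, 3))
  ffit <- fit_intensity_decay(sw, 1)
  expect_true(ffit$converged)
  expect_equal(ffit$model$lifetimes_ns, 3, tolerance = 1e-8)
  expect_lt(ffit$chi_sq_reduced, 1e-12)

  tr <- gen_polarized_decay(decay_model(1, 3), NULL, g_factor = 1.2)
  tfit <- fit_intensity_decay(tr, 1)
  expect_equal(tfit$model$lifetimes_ns, 3, tolerance = 1e-8)
  expect_equal(sum(tfit$model$amplitudes), 1, tolerance = 1e-9)
})

test_that("two-component decays are recovered and amplitudes stay normalised", {
  dm <- decay_model(c(0.7, 0.3), c(1, 5))
  sw <- gen_frequency_sweep(dm, freq_mhz = exp(seq(log(2), log(500),
                                                   length.out = 25)))
  fit <- fit_intensity_decay(sw, 2)
  expect_equal(fit$model$lifetimes_ns, c(1, 5), tolerance = 1e-6)
  expect_equal(fit$model$amplitudes, c(0.7, 0.3), tolerance = 1e-6)
  expect_equal(sum(fit$model$amplitudes), 1, tolerance = 1e-9)

  tr <- gen_polarized_decay(dm, NULL)
  tfit <- fit_intensity_decay(tr, 2)
  expect_equal(tfit$model$lifetimes_ns, c(1, 5), tolerance = 1e-6)
})

test_that("noisy two-component sweeps recover the slow lifetime without bias", {
  dm <- decay_model(c(0.7, 0.3), c(1, 5))
  freqs <- exp(seq(log(2), log(500), length.out = 25))
  tau2 <- vapply(seq_len(200), function(i) {
    sw <- gen_frequency_sweep(dm, freq_mhz = freqs,
                              noise = noise_spec(0.002, seed = i))
    fit_intensity_decay(sw, 2)$model$lifetimes_ns[2]
  }, numeric(1))
  expect_lt(abs(median(tau2) - 5) / 5, 0.02)
})

test_that("average lifetime follows the stated weightings", {
  m1 <- decay_model(1, 3)
  expect_equal(average_lifetime(m1, "amplitude"), 3)
  expect_equal(average_lifetime(m1, "intensity"), 3)
  m2 <- decay_model(c(0.7, 0.3), c(1, 5))
  expect_equal(average_lifetime(m2, "amplitude"), 2.2)
  expect_equal(average_lifetime(m2, "intensity"), (0.7 + 7.5) / 2.2)
})

test_that("anisotropy trace reproduces the model r(t) with G applied", {
  am <- anisotropy_model(0.2, 35.9)
  # lifetime long enough that the intensity floor keeps t = 35.9 ns in view
  tr <- gen_polarized_decay(decay_model(1, 10), am, g_factor = 1,
                            time_ns = seq(0, 40, length.out = 4096))
  rt <- compute_anisotropy_trace(tr)
  expect_equal(rt$r[1], 0.2, tolerance = 1e-10)
  # r at t = phi equals r0 / e
  r_at_phi <- approx(rt$time_ns, rt$r, xout = 35.9)$y
  expect_equal(r_at_phi, 0.2 / exp(1), tolerance = 1e-6)
  # isotropic emission gives r identically zero
  iso <- data.frame(time_ns = 0:10, i_vv = rep(1, 11), i_vh = rep(1, 11))
  expect_true(all(compute_anisotropy_trace(iso)$r == 0))
  # G perturbation identity: r with G = 1.1 equals r after rescaling i_vh
  tr2 <- tr
  tr2$i_vh <- tr$i_vh / 1.1
  r_g <- compute_anisotropy_trace(tr2, g_factor = 1.1)
  expect_equal(r_g$r, rt$r, tolerance = 1e-12)
  expect_error(compute_anisotropy_trace(
    data.frame(time_ns = 0:3, i_vv = rep(0, 4), i_vh = rep(0, 4))),
    "all-zero")
})

test_that("anisotropy decay fits recover ground truth", {
  # single component, noiseless: exact
  tr <- gen_polarized_decay(decay_model(1, 4), anisotropy_model(0.3, 10),
                            time_ns = seq(0, 60, length.out = 1024))
  fit <- fit_anisotropy_decay(compute_anisotropy_trace(tr), 1)
  expect_equal(fit$model$r0, 0.3, tolerance = 1e-7)
  expect_equal(fit$model$phi_ns, 10, tolerance = 1e-7)
  # double exponential with a slow 35.9 ns component
  tr2 <- gen_polarized_decay(decay_model(1, 2.92),
                             anisotropy_model(c(0.1, 0.15), c(0.5, 35.9)),
                             time_ns = seq(0, 150, length.out = 2048))
  fit2 <- fit_anisotropy_decay(compute_anisotropy_trace(tr2), 2)
  expect_equal(max(fit2$model$phi_ns), 35.9, tolerance = 1e-6)
  # sub-grid correlation times are flagged as resolution-limited
  coarse <- gen_polarized_decay(decay_model(1, 4),
                                anisotropy_model(c(0.1, 0.2), c(0.3, 12)),
                                time_ns = seq(0, 30, length.out = 100))
  fit3 <- fit_anisotropy_decay(compute_anisotropy_trace(coarse), 2)
  expect_true("resolution-limited" %in% fit3$flags)
})

test_that("noisy anisotropy fits recover a 6.9 ns correlation time", {
  phi_hat <- vapply(seq_len(100), function(i) {
    tr <- gen_polarized_decay(decay_model(1, 3.26), anisotropy_model(0.2, 6.9),
                              time_ns = seq(0, 40, length.out = 512),
                              noise = noise_spec(0.005, seed = 2000 + i))
    fit_anisotropy_decay(compute_anisotropy_trace(tr), 1)$model$phi_ns
  }, numeric(1))
  expect_lt(abs(median(phi_hat) - 6.9) / 6.9, 0.05)
})

test_that("G factor and steady-state anisotropy follow their definitions", {
  expect_equal(g_factor(1, 1), 1)
  expect_equal(g_factor(1.2, 1.0), 1.2)
  expect_error(g_factor(1, 0), "> 0")
  expect_equal(steady_state_anisotropy(1, 1, g = 1), 0)
  # G = 1 reduces to the uncorrected formula
  expect_equal(steady_state_anisotropy(1.3, 0.7, g = 1),
               (1.3 - 0.7) / (1.3 + 2 * 0.7))
  # constructed intensities reproduce a target anisotropy under G correction
  r <- 0.083; g <- 1.1
  expect_equal(steady_state_anisotropy((1 + 2 * r) / 3, (1 - r) / (3 * g), g),
               r, tolerance = 1e-14)
  expect_error(steady_state_anisotropy(-1, 1), ">= 0")
})

test_that("steady-state anisotropy equals the intensity-weighted r(t) average", {
  dm <- decay_model(c(0.6, 0.4), c(2, 6))
  am <- anisotropy_model(c(0.12, 0.1), c(1, 25))
  grid <- seq(0, 120, length.out = 20000)
  tr <- gen_polarized_decay(dm, am, time_ns = grid)
  i_vv_tot <- trapz(grid, tr$i_vv)
  i_vh_tot <- trapz(grid, tr$i_vh)
  r_ss <- steady_state_anisotropy(i_vv_tot, i_vh_tot, g = 1)
  itot <- oracle_decay(dm$amplitudes, dm$lifetimes_ns, grid)
  r_t <- vapply(seq_along(grid), function(i)
    sum(am$r0 * exp(-grid[i] / am$phi_ns)), numeric(1))
  r_oracle <- trapz(grid, itot * r_t) / trapz(grid, itot)
  expect_equal(r_ss, r_oracle, tolerance = 1e-4)
})

test_that("frequency-domain response obeys its monotonicity laws", {
  # modulation is strictly decreasing for every decay mixture; phase is
  # strictly increasing for a single component (tan phi = omega tau) but can
  # dip by a fraction of a degree for strongly heterogeneous mixtures, so
  # only boundedness is asserted for multi-component models
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:3, 1)
    dm <- decay_model(runif(n, 0.1, 1), sort(runif(n, 0.3, 20)))
    sw <- gen_frequency_sweep(dm, freq_mhz = exp(seq(log(1), log(500),
                                                     length.out = 40)))
    expect_true(all(diff(sw$modulation) < 0))
    if (n == 1) expect_true(all(diff(sw$phase_deg) > 0))
    expect_true(all(sw$phase_deg >= 0 & sw$phase_deg < 90))
    expect_true(all(sw$modulation > 0 & sw$modulation <= 1))
  }
})

test_that("overparameterised fits are flagged rather than trusted", {
  sw <- gen_frequency_sweep(decay_model(1, 3),
                            freq_mhz = exp(seq(log(2), log(500),
                                               length.out = 20)),
                            noise = noise_spec(0.002, seed = 5))
  fit <- fit_intensity_decay(sw, 2)
  expect_true("overparameterised" %in% fit$flags || fit$converged)
  expect_error(fit_intensity_decay(sw, 4), "1, 2 or 3")
})
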