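# Generators: analytic identities, independent oracles, determinism and
# noise-scaling behaviour.

test_that("polarized decay generator satisfies the magic-sum identity", {
  dm <- decay_model(c(0.5, 0.5), c(1, 5))
  am <- anisotropy_model(c(0.1, 0.15), c(0.8, 20))
  for (g in c(1, 1.17)) {
    tr <- gen_polarized_decay(dm, am, g_factor = g)
    itot <- oracle_decay(dm$amplitudes, dm$lifetimes_ns, tr$time_ns)
    expect_lt(max(abs(tr$i_vv + 2 * g * tr$i_vh - itot) / itot), 1e-10)
  }
  # zero anisotropy, G = 1: both channels are I(t)/3
  tr0 <- gen_polarized_decay(decay_model(1, 3), NULL)
  expect_equal(tr0$i_vv, exp(-tr0$time_ns / 3) / 3, tolerance = 1e-12)
  expect_equal(tr0$i_vh, tr0$i_vv, tolerance = 1e-12)
  # direct-evaluation oracle at t = 2 ns for a two-component decay
  tr2 <- gen_polarized_decay(decay_model(c(0.5, 0.5), c(1, 5)), NULL,
                             time_ns = c(0, 2))
  expect_equal(tr2$i_vv[2] + 2 * tr2$i_vh[2],
               0.5 * exp(-2) + 0.5 * exp(-0.4), tolerance = 1e-12)
})

test_that("polarized decay generator rejects invalid input", {
  expect_error(gen_polarized_decay(decay_model(1, 3), time_ns = c(1, 1, 2)),
               "strictly increasing")
  expect_error(anisotropy_model(c(0.3, 0.2), c(1, 10)), "0.4")
  expect_error(gen_polarized_decay(decay_model(1, 3), g_factor = 0), "> 0")
})

test_that("frequency sweep matches single-exponential closed forms", {
  # omega * tau = 1 at f = 1000 / (2 pi tau) MHz: phase 45 deg, m = 1/sqrt(2)
  tau <- 3
  f1 <- 1000 / (2 * pi * tau)
  sw <- gen_frequency_sweep(decay_model(1, tau), freq_mhz = c(f1, 2 * f1))
  expect_equal(sw$phase_deg[1], 45, tolerance = 1e-10)
  expect_equal(sw$modulation[1], 1 / sqrt(2), tolerance = 1e-10)
  # closed-form evaluation at 80 MHz for tau = 2.92 ns
  wt <- 2 * pi * 80e6 * 2.92e-9
  sw2 <- gen_frequency_sweep(decay_model(1, 2.92), freq_mhz = 80)
  expect_equal(sw2$phase_deg, atan(wt) * 180 / pi, tolerance = 1e-12)
  expect_equal(sw2$modulation, 1 / sqrt(1 + wt^2), tolerance = 1e-12)
})

test_that("frequency sweep agrees with numeric Fourier quadrature", {
  a <- c(0.7, 0.3); tau <- c(1, 5)
  sw <- gen_frequency_sweep(decay_model(a, tau), freq_mhz = 50)
  orc <- oracle_phase_mod(a, tau, 50)
  expect_equal(sw$phase_deg, orc$phase_deg, tolerance = 1e-6)
  expect_equal(sw$modulation, orc$modulation, tolerance = 1e-6)
})

test_that("frequency sweep rejects empty or invalid frequency lists", {
  expect_error(gen_frequency_sweep(decay_model(1, 3), freq_mhz = numeric()),
               "empty")
  expect_error(gen_frequency_sweep(decay_model(1, 3), freq_mhz = c(10, 5)),
               "increasing")
})

test_that("pyrene curve has the documented plateau and midpoint slope", {
  tgrid <- seq(0, 2000, length.out = 2000)
  tr1 <- gen_pyrene_curve(f0 = 0.1, fmax = 1.1, t_half_s = 600,
                          steepness = 0.01, plateau_scale = 1, time_s = tgrid)
  expect_true(all(diff(tr1$intensity_au) >= 0))
  expect_equal(max(tr1$intensity_au), 1.1, tolerance = 1e-4)
  # plateau scaling: ratio of amplitudes equals the scale factor
  tr4 <- gen_pyrene_curve(f0 = 0.1, fmax = 1.1, t_half_s = 600,
                          steepness = 0.01, plateau_scale = 4, time_s = tgrid)
  expect_equal((max(tr4$intensity_au) - 0.1) / (max(tr1$intensity_au) - 0.1),
               4, tolerance = 1e-3)
  # analytic midpoint slope vs central finite difference at t_half
  h <- 1e-4 * 600
  num <- (actospec:::.pyrene_curve(600 + h, 0.1, 1.1, 600, 0.01, 1) -
          actospec:::.pyrene_curve(600 - h, 0.1, 1.1, 600, 0.01, 1)) / (2 * h)
  expect_equal(num, 1 * 0.01 / 4, tolerance = 1e-6)
  expect_error(gen_pyrene_curve(steepness = 0), "> 0")
})

test_that("cc series is the exact piecewise line and warns when degenerate", {
  bm <- breakpoint_model(5, 0.1, 2.0, 0.5)
  s <- gen_cc_series(bm, conc_um = c(0.1, 0.3, 0.5, 0.7, 1))
  # hand evaluation above the breakpoint: F(1) = f_c + 2.0 * (1 - 0.5)
  expect_equal(s$intensity_au[5], 5 + 2.0 * 0.5, tolerance = 1e-12)
  # equal slopes give a single straight line
  line <- gen_cc_series(breakpoint_model(5, 2, 2, 0.5),
                        conc_um = c(0.1, 0.3, 0.5, 0.7, 1))
  fit <- lm(intensity_au ~ conc_um, data = line)
  expect_lt(max(abs(resid(fit))), 1e-12)
  expect_warning(gen_cc_series(breakpoint_model(5, 0.1, 2, 10),
                               conc_um = c(0.1, 0.5, 1, 2, 5)),
                 "unidentifiable")
})

test_that("FRET spectra encode the transfer efficiency in the band area", {
  # E = 0: donor-only and acceptor-present spectra identical
  sp0 <- gen_fret_spectra(data.frame(temperature_c = 10, efficiency = 0))
  expect_equal(sp0[[1]]$intensity_au, sp0[[2]]$intensity_au)
  # area ratio equals 1 - E for a range of efficiencies
  for (e in c(0.26, 0.5)) {
    sp <- gen_fret_spectra(data.frame(temperature_c = 10, efficiency = e))
    ratio <- integrate_band(sp[[2]]) / integrate_band(sp[[1]])
    expect_equal(ratio, 1 - e, tolerance = 1e-6)
  }
  # fine-grid quadrature oracle: area of the scaled Gaussian is half
  fine <- seq(380, 600, by = 0.05)
  sp5 <- gen_fret_spectra(data.frame(temperature_c = 10, efficiency = 0.5),
                          wavelength_nm = fine)
  expect_equal(trapz(fine, sp5[[2]]$intensity_au),
               trapz(fine, sp5[[1]]$intensity_au) / 2, tolerance = 1e-10)
  expect_error(gen_fret_spectra(data.frame(temperature_c = 1, efficiency = 1)),
               "E < 1")
})

test_that("NADH trace slope follows the unit chain", {
  # k = 0.2 /s at 0.5 uM motor and eps*l = 6220 /M: slope -6.22e-4 A/s
  tr <- gen_nadh_trace(0.2, hmm_um = 0.5, eps_path = 6220)
  slope <- coef(lm(a340 ~ time_s, data = tr))[[2]]
  expect_equal(slope, -6.22e-4, tolerance = 1e-10)
  # no hydrolysis: flat trace at the initial absorbance
  flat <- gen_nadh_trace(0, a0 = 0.9)
  expect_true(all(flat$a340 == 0.9))
  expect_error(gen_nadh_trace(0.1, duration_s = -1), "> 0")
})

test_that("identical seed and parameters give bit-identical output", {
  gens <- list(
    function(n) gen_polarized_decay(decay_model(1, 3),
                                    anisotropy_model(0.2, 10), noise = n),
    function(n) gen_frequency_sweep(decay_model(1, 3), noise = n),
    function(n) gen_pyrene_curve(noise = n),
    function(n) gen_cc_series(breakpoint_model(5, 0.5, 10, 0.5), noise = n),
    function(n) gen_stopped_flow(biexp_model(0.6, 0.4, 0.05, 0.8), noise = n),
    function(n) gen_nadh_trace(0.1, noise = n))
  for (g in gens) {
    a <- g(noise_spec(0.01, seed = 42))
    b <- g(noise_spec(0.01, seed = 42))
    expect_identical(serialize(a, NULL), serialize(b, NULL))
    c <- g(noise_spec(0.01, seed = 43))
    expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
  }
})

test_that("recovery RMSE grows monotonically with the noise level", {
  sigmas <- c(5e-4, 5e-3, 5e-2)
  rmse <- vapply(sigmas, function(sg) {
    err <- vapply(seq_len(200), function(i) {
      tr <- gen_nadh_trace(0.164, hmm_um = 0.5,
                           noise = noise_spec(sg, seed = 1000 + i))
      k <- atpase_rate(fit_a340_slope(tr)$slope_abs_per_s,
                       hmm_um = 0.5)$rate_k
      k - 0.164
    }, numeric(1))
    sqrt(mean(err^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
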