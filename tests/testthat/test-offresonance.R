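# Off-resonance rotating-frame analysis: effective-field geometry, the K
# factor and its inversion, profile fitting.

cfg <- spectrometer_config()

test_that("offset-to-field conversion matches the algebraic identities", {
  expect_equal(delta_b(0, cfg), 0)
  # an offset equal to the nutation frequency maps to a field equal to B1
  expect_equal(delta_b(cfg$nutation_hz, cfg), cfg$b1_tesla, tolerance = 1e-12)
  expect_equal(delta_b(21288.74, cfg), 5.0000e-4, tolerance = 1e-4)
  expect_equal(delta_b(-21288.74, cfg), -5.0000e-4, tolerance = 1e-4)
})

test_that("tilt angle spans (0, pi/2] with the defined on-resonance limit", {
  expect_identical(tilt_angle(0, cfg), pi / 2)
  expect_equal(tilt_angle(cfg$nutation_hz, cfg), pi / 4, tolerance = 1e-12)
  expect_lt(tilt_angle(1e9, cfg), 1e-4)
})

test_that("K factor hits its closed-form limits and printed-table values", {
  expect_equal(compute_k_factor(0, cfg), 1)
  # reference values at 30.2 MHz, within the tabulated fit uncertainties
  expect_equal(compute_k_factor(1.8e-9, cfg), 1.22, tolerance = 0.17 / 1.22)
  expect_equal(compute_k_factor(3.6e-9, cfg), 1.72, tolerance = 0.21 / 1.72)
  # frozen full-precision values from direct evaluation of the rational form
  expect_equal(compute_k_factor(1.8e-9, cfg), 1.2202122, tolerance = 1e-6)
  expect_equal(compute_k_factor(3.6e-9, cfg), 1.7106507, tolerance = 1e-6)
  # slow-motion asymptote: K / (omega tau)^2 -> 12/16
  tau <- 1e-5
  expect_equal(compute_k_factor(tau, cfg) / (cfg$omega0 * tau)^2, 0.75,
               tolerance = 1e-3)
  expect_error(compute_k_factor(-1e-9, cfg), "non-negative")
})

test_that("every reference (K, tau_c) pair is consistent within its uncertainty", {
  ref <- reference_offresonance()
  for (i in seq_len(nrow(ref))) {
    expect_lt(abs(compute_k_factor(ref$tau_c_ns[i] * 1e-9, cfg) - ref$K[i]),
              ref$K_err[i])
  }
})

test_that("K is strictly increasing in tau_c, guaranteeing a unique inverse", {
  taus <- seq(0, 100e-9, length.out = 2000)
  expect_true(all(diff(compute_k_factor(taus, cfg)) > 0))
  expect_true(all(compute_k_factor(taus, cfg) >= 1))
})

test_that("inversion round-trips the forward map to 1e-9 relative", {
  for (tau in c(1e-12, 1e-10, 1e-9, 3.2e-9, 1e-8, 1e-7)) {
    got <- invert_k_for_tau(compute_k_factor(tau, cfg), cfg)$tau_c
    expect_equal(got, tau, tolerance = 1e-9)
  }
  expect_equal(invert_k_for_tau(1, cfg)$tau_c, 0)
})

test_that("inversion agrees with an independent dense-grid oracle", {
  # oracle: nearest neighbour on a fine tau grid, no root finder involved
  taus <- seq(0.1e-9, 10e-9, by = 1e-13)
  ks <- compute_k_factor(taus, cfg)
  for (k in c(1.22, 1.46, 1.61, 1.72)) {
    oracle <- taus[which.min(abs(ks - k))]
    expect_equal(invert_k_for_tau(k, cfg)$tau_c, oracle, tolerance = 1e-3)
  }
  # frozen values: tau_c(K = 1.61) and tau_c(K = 1.46) in ns
  expect_equal(invert_k_for_tau(1.61, cfg)$tau_c * 1e9, 3.26870,
               tolerance = 1e-4)
  expect_equal(invert_k_for_tau(1.46, cfg)$tau_c * 1e9, 2.74904,
               tolerance = 1e-4)
})

test_that("inversion rejects out-of-domain K and reports the regime diagnostic", {
  expect_error(invert_k_for_tau(0.97, cfg), "below its theoretical minimum")
  expect_error(invert_k_for_tau(2, cfg, tau_max = 1e-12), "exceeds")
  res <- invert_k_for_tau(1.61, cfg)
  expect_equal(res$omega_tau, cfg$omega0 * res$tau_c)
  expect_lt(res$omega_e_tau, 0.1) # study regime: omega_e * tau_c << 1
  expect_warning(invert_k_for_tau(1e5, cfg, tau_max = 1e-3), "fast-motion")
})

test_that("ratio model is monotone in |offset| and in K", {
  f <- seq(1e2, 1e6, length.out = 200)
  r <- model_offres_ratio(f, 1.5, cfg)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
  expect_true(all(model_offres_ratio(f, 1.2, cfg) >
                    model_offres_ratio(f, 1.7, cfg)))
  expect_equal(model_offres_ratio(0, 1.5, cfg), 0)
  expect_equal(model_offres_ratio(cfg$nutation_hz * sqrt(1.5), 1.5, cfg), 0.5,
               tolerance = 1e-12)
})

test_that("zero-noise profiles recover K exactly; noisy ones within the median band", {
  f <- fit_k(gen_offres_profile(3.6e-9, cfg), cfg)
  expect_equal(f$k, compute_k_factor(3.6e-9, cfg), tolerance = 1e-6)

  # repeated-seed medians at 2% noise (single-seed spread is about twice this)
  k_true <- compute_k_factor(1.8e-9, cfg)
  k_errs <- vapply(1:40, function(s) {
    abs(fit_k(gen_offres_profile(1.8e-9, cfg,
                                 noise = noise_spec(0.02, seed = s)), cfg)$k -
          k_true)
  }, numeric(1))
  expect_lt(stats::median(k_errs), 0.05)

  tau_errs <- vapply(1:40, function(s) {
    pr <- gen_offres_profile(2.8e-9, cfg, noise = noise_spec(0.02, seed = s))
    abs(analyze_offresonance(pr, cfg)$tau$tau_c - 2.8e-9)
  }, numeric(1))
  expect_lt(stats::median(tau_errs), 0.3e-9)
})

test_that("profile fitting rejects unconstraining inputs", {
  sat <- offres_profile(cfg$nutation_hz * c(20, 40, 80, 160, 320, 640, 1280),
                        rep(0.999, 7))
  expect_error(fit_k(sat, cfg), "too large to constrain")
  few <- gen_offres_profile(2e-9, cfg, offsets = default_offsets(cfg, n = 5L))
  expect_error(fit_k(few, cfg), "at least 6")
})

test_that("analyze_offresonance composes fit and inversion", {
  res <- analyze_offresonance(gen_offres_profile(3.2e-9, cfg), cfg)
  expect_equal(res$k_fit$k, compute_k_factor(3.2e-9, cfg), tolerance = 1e-6)
  expect_equal(res$tau$tau_c, 3.2e-9, tolerance = 1e-6)
  res0 <- analyze_offresonance(gen_offres_profile(0, cfg), cfg)
  expect_equal(res0$k_fit$k, 1, tolerance = 1e-6)
  expect_equal(res0$tau$tau_c, 0, tolerance = 1e-12)
})
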