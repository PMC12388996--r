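# Laboratory-frame fits: model evaluation, exact recovery at zero noise,
# tolerance-bounded recovery under noise, invariants.

test_that("recovery and mixture models evaluate to known values", {
  expect_equal(model_t1(2.5 * log(2), 2.5, 1), 0.5, tolerance = 1e-12)
  expect_equal(model_t1(0, 2.5, 1), 0)
  expect_equal(model_t1(2.5, 2.5, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_error(model_t1(1, -2, 1), "t1")

  expect_equal(model_t2_mixture(0, 77, 0.232, 0.0076, 3), 3, tolerance = 1e-12)
  expect_equal(model_t2_mixture(0.2, 100, 0.2, 0.05, 1), exp(-1),
               tolerance = 1e-12)
  expect_error(model_t2_mixture(0, 120, 0.2, 0.05), "0, 100")
})

test_that("zero-noise fits recover the generating parameters exactly", {
  f1 <- fit_t1(gen_t1_curve(2.5))
  expect_equal(f1$t1, 2.5, tolerance = 1e-6)
  expect_equal(f1$m0, 1, tolerance = 1e-6)

  f2 <- fit_t2_mixture(gen_t2_decay(86, 0.188, 0.118))
  expect_equal(f2$m0g_percent, 86, tolerance = 0.1)
  expect_equal(f2$t2g, 0.188, tolerance = 1e-3 * 0.188)
  expect_equal(f2$t2l, 0.118, tolerance = 1e-3 * 0.118)
})

test_that("fit(model(theta)) = theta over a grid of realistic parameter sets", {
  grid <- expand.grid(frac = c(58, 62, 77, 86),
                      t2g = c(0.184, 0.232),
                      t2l = c(0.0076, 0.118, 0.352))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    f <- fit_t2_mixture(gen_t2_decay(g$frac, g$t2g, g$t2l))
    expect_equal(f$m0g_percent, g$frac, tolerance = 0.5)
    expect_equal(f$t2g, g$t2g, tolerance = 0.01 * g$t2g)
    expect_equal(f$t2l, g$t2l, tolerance = 0.01 * g$t2l)
    expect_equal(f$m0g_percent + f$m0l_percent, 100, tolerance = 1e-9)
  }
  for (t1 in c(2.5, 2.6, 2.7)) {
    expect_equal(fit_t1(gen_t1_curve(t1))$t1, t1, tolerance = 1e-5 * t1)
  }
})

test_that("noisy recovery stays within simulation-derived tolerances", {
  f1 <- fit_t1(gen_t1_curve(2.7, noise = noise_spec(0.01, seed = 101)))
  expect_lt(abs(f1$t1 - 2.7) / 2.7, 0.05)

  f2 <- fit_t2_mixture(gen_t2_decay(77, 0.232, 0.0076,
                                    noise = noise_spec(0.01, seed = 101)))
  expect_lt(abs(f2$t2g - 0.232) / 0.232, 0.05)
  expect_lt(abs(f2$t2l - 0.0076) / 0.0076, 0.15)
})

test_that("fitted residual RMS is bounded by the injected noise level", {
  f1 <- fit_t1(gen_t1_curve(2.5, noise = noise_spec(0.02, seed = 8)))
  expect_lt(f1$rms, 0.02 * 1.5)
  f2 <- fit_t2_mixture(gen_t2_decay(77, 0.232, 0.0076,
                                    noise = noise_spec(0.02, seed = 8)))
  expect_lt(f2$rms, 0.02 * 1.5)
})

test_that("mixture time constants are invariant to magnetization rescaling", {
  times <- default_t2_times(0.232, 0.0076)
  base <- gen_t2_decay(77, 0.232, 0.0076, times = times,
                       noise = noise_spec(0.01, seed = 13))
  scaled <- relaxation_curve(times, base$M * 37.5, kind = "transverse_decay")
  fa <- fit_t2_mixture(base)
  fb <- fit_t2_mixture(scaled)
  expect_equal(fb$t2g, fa$t2g, tolerance = 1e-6)
  expect_equal(fb$t2l, fa$t2l, tolerance = 1e-6)
  expect_equal(fb$m0g_percent, fa$m0g_percent, tolerance = 1e-6)
  expect_equal(fb$m0_total, fa$m0_total * 37.5, tolerance = 1e-6)
})

test_that("a single-exponential decay yields a vanishing Gaussian fraction", {
  f <- fit_t2_mixture(gen_t2_decay(0, 0.2, 0.05))
  expect_lte(f$m0g_percent, 1)
})

test_that("near-degenerate time constants collapse to a flagged single fit", {
  f <- fit_t2_mixture(gen_t2_decay(50, 0.2, 0.205))
  expect_true(f$degenerate)
  expect_true(f$m0g_percent %in% c(0, 100))
})

test_that("degenerate inputs raise fit-failure errors naming the curve", {
  flat <- relaxation_curve(1:10, rep(0, 10), kind = "saturation_recovery",
                           label = "flatline")
  expect_error(fit_t1(flat), "flatline")
  expect_error(fit_t1(gen_t2_decay(50, 0.2, 0.05)), "saturation-recovery")
  expect_error(fit_t2_mixture(gen_t1_curve(2.5)), "transverse-decay")
  short <- relaxation_curve(1:10, exp(-(1:10) / 3), kind = "transverse_decay")
  expect_error(fit_t2_mixture(short), "12 points")
})

test_that("report layout converts units and aligns materials", {
  t1f <- list(A = fit_t1(gen_t1_curve(2.5)))
  t2f <- list(A = fit_t2_mixture(gen_t2_decay(77, 0.232, 0.0076)))
  rep <- relaxation_report(t1f, t2f)
  expect_equal(rep$T1_s, 2.5, tolerance = 1e-5)
  expect_equal(rep$T2G_ms, 232, tolerance = 0.5)
  expect_equal(rep$T2L_ms, 7.6, tolerance = 0.05)
})
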