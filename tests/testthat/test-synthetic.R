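# Generators: closed-form agreement at zero noise, determinism, cardinality.

test_that("zero-noise generators reproduce the closed-form models exactly", {
  # saturation recovery: 1 - e^-5 at t = 5*T1
  cu <- gen_t1_curve(2.5, m0 = 1, times = c(0.01, 0.1, 0.5, 1, 2, 4, 8, 12.5))
  expect_equal(cu$M[8], 0.993262053, tolerance = 1e-9)
  expect_equal(cu$M, 1 - exp(-cu$t_s / 2.5), tolerance = 1e-12)

  # transverse mixture: pure components hit m0/e at their own time constant
  tg <- default_t2_times(0.2, 0.2)
  expect_equal(gen_t2_decay(100, 0.2, 0.05, times = sort(c(tg, 0.2)))$M[
    which(sort(c(tg, 0.2)) == 0.2)], exp(-1), tolerance = 1e-12)
  tl <- sort(c(default_t2_times(0.2, 0.05), 0.05))
  expect_equal(gen_t2_decay(0, 0.2, 0.05, times = tl)$M[which(tl == 0.05)],
               exp(-1), tolerance = 1e-12)

  # mixture value frozen from direct evaluation of the two-kernel model at
  # the 58%/184ms/42%/300ms parameter set, t = 184 ms
  expect_equal(model_t2_mixture(0.184, 58, 0.184, 0.300, 1),
               0.4408180, tolerance = 1e-6)

  # off-resonance: half saturation at (gamma/2pi) B1 sqrt(K)
  cfg <- spectrometer_config()
  k <- compute_k_factor(1.8e-9, cfg)
  pr <- gen_offres_profile(1.8e-9, cfg,
                           offsets = sort(c(default_offsets(cfg),
                                            cfg$nutation_hz * sqrt(k))))
  expect_equal(pr$ratio[abs(pr$delta_f_hz - cfg$nutation_hz * sqrt(k)) < 1e-9],
               0.5, tolerance = 1e-12)
  expect_true(all(pr$ratio >= 0 & pr$ratio < 1))

  # dose-response: definition of IC50 and of the untreated control
  d <- gen_dose_response(5, 1, concentrations = c(0.5, 1, 5, 45),
                         n_replicates = 1L)
  expect_equal(d$viability_pct[d$conc_um == 5], 50)
  expect_equal(d$viability_pct[d$conc_um == 45], 10, tolerance = 1e-12)
  expect_equal(model_viability(0, 5, 1), 100)
})

test_that("identical seeds give bit-identical outputs, different seeds differ", {
  n1 <- noise_spec(0.02, seed = 123)
  a <- gen_t1_curve(2.5, noise = n1)
  b <- gen_t1_curve(2.5, noise = noise_spec(0.02, seed = 123))
  expect_identical(a$M, b$M)
  expect_false(identical(a$M, gen_t1_curve(2.5, noise = noise_spec(0.02, 124))$M))

  p1 <- gen_offres_profile(2e-9, noise = noise_spec(0.02, seed = 5))
  p2 <- gen_offres_profile(2e-9, noise = noise_spec(0.02, seed = 5))
  expect_identical(p1$ratio, p2$ratio)

  d1 <- gen_dose_response(5, 1.5, noise = noise_spec(0.05, seed = 9))
  d2 <- gen_dose_response(5, 1.5, noise = noise_spec(0.05, seed = 9))
  expect_identical(d1$viability_pct, d2$viability_pct)

  t1 <- gen_dls_table(2, 2, noise = noise_spec(0.05, seed = 77))
  t2 <- gen_dls_table(2, 2, noise = noise_spec(0.05, seed = 77))
  expect_identical(t1, t2)
})

test_that("seeded generation does not disturb the session RNG stream", {
  set.seed(1)
  before <- .Random.seed
  invisible(gen_t1_curve(2.5, noise = noise_spec(0.01, seed = 42)))
  expect_identical(.Random.seed, before)
})

test_that("characterization-table generator respects cardinality and means", {
  tab <- gen_dls_table(4, 4, size_mean = 126.0, pdi_mean = 0.17,
                       zeta_mean = 33.3)
  expect_equal(nrow(tab), 16L)
  expect_true(all(tab$size_nm == 126.0))
  expect_true(all(tab$pdi == 0.17))
  expect_true(all(tab$zeta_mv == 33.3))
})

test_that("generators validate their parameters", {
  expect_error(gen_t1_curve(-1), "t1 and m0")
  expect_error(gen_t1_curve(2.5, m0 = 0), "t1 and m0")
  expect_error(gen_t2_decay(101, 0.2, 0.05), "0, 100")
  expect_error(gen_offres_profile(-1e-9), "tau_c")
  expect_error(gen_dose_response(0, 1), "ic50 and hill")
  expect_error(gen_dls_table(0, 4), ">= 1")
  expect_error(noise_spec(-0.1), "sigma_relative")
})

test_that("fixture round-trips preserve data and metadata", {
  tmp <- tempfile(fileext = ".csv")
  cu <- gen_t1_curve(2.5, noise = noise_spec(0.01, seed = 2), label = "demo")
  write_relaxation_curve(cu, tmp)
  back <- read_relaxation_curve(tmp)
  expect_equal(back$M, cu$M, tolerance = 1e-12)
  expect_identical(attr(back, "kind"), "saturation_recovery")
  expect_identical(attr(back, "label"), "demo")

  pr <- gen_offres_profile(2e-9, label = "p")
  tmp2 <- tempfile(fileext = ".csv")
  write_offres_profile(pr, tmp2)
  expect_equal(read_offres_profile(tmp2)$ratio, pr$ratio, tolerance = 1e-12)

  tmp3 <- tempfile(fileext = ".csv")
  write_fixture_csv(cu, tmp3, seed = 2)
  expect_match(readLines(tmp3, n = 1L), "seed: 2")
  long <- utils::read.csv(tmp3, comment.char = "#")
  expect_equal(long$y, cu$M, tolerance = 1e-12)
})
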