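test_that("generators are bit-identical under a fixed seed", {
  m <- multi_exp_model(c(100, 10), c(0.5, 4))
  g1 <- generate_decay(m, 1e5, n_channels = 512, channel_width_ps = 50,
                       seed = 42)
  g2 <- generate_decay(m, 1e5, n_channels = 512, channel_width_ps = 50,
                       seed = 42)
  expect_identical(g1$hist$counts, g2$hist$counts)
  g3 <- generate_decay(m, 1e5, n_channels = 512, channel_width_ps = 50,
                       seed = 43)
  expect_false(identical(g1$hist$counts, g3$hist$counts))

  f1 <- generate_fcs_curve(fcs_model(0.1, 0.24), seed = 7)
  f2 <- generate_fcs_curve(fcs_model(0.1, 0.24), seed = 7)
  expect_identical(f1$curve$G, f2$curve$G)

  t1 <- generate_blinking_trace(duration_s = 0.2, seed = 9)
  t2 <- generate_blinking_trace(duration_s = 0.2, seed = 9)
  expect_identical(t1$intensity, t2$intensity)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(3)
  set.seed(1234)
  invisible(generate_decay(multi_exp_model(100, 2), 1e4, n_channels = 512,
                           channel_width_ps = 50, seed = 5))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("generated decay totals concentrate around the request", {
  m <- multi_exp_model(c(10000, 1000, 1), c(0.115, 2.2, 16.3))
  for (seed in 1:3) {
    g <- generate_decay(m, total_counts = 2e5, n_channels = 1024,
                        channel_width_ps = 50, seed = seed)
    expect_lt(abs(sum(g$hist$counts) - 2e5), 4 * sqrt(2e5))
    # embedded truth reproduces the expectation that generated the data
    mu <- reconvolve(g$truth, g$irf, 1024)
    expect_equal(sum(mu), 2e5, tolerance = 1e-6)
  }
  expect_error(generate_decay(m, total_counts = 10))
})

test_that("noise-free FCS curves equal the model exactly", {
  truth <- fcs_model(0.1, 0.24, 5, 0.15, 7)
  g <- generate_fcs_curve(truth, noise = 0, seed = 1)
  expect_equal(g$curve$G, fcs_eval(truth, g$curve$lags_s))
})

test_that("FCS round trip recovers the diffusion time within 10%", {
  truth <- fcs_model(0.1, 0.24, 5, 0.15, 7)
  g <- generate_fcs_curve(truth, noise = 0.02, seed = 11)
  fit <- fit_fcs(g$curve)
  expect_lt(abs(coef(fit)[["tauD_ms"]] / g$truth$tauD_ms - 1), 0.1)
})

test_that("spectra generator implements the dark-dimer model", {
  b <- spectral_basis()
  pure <- generate_spectra(0, b, noise = 0, seed = 1)
  expect_equal(pure$absorption$values, b$monomer$values)
  dark <- generate_spectra(1, b, noise = 0, seed = 1)
  expect_lt(max(dark$excitation$values), 1e-12)
  expect_lt(max(dark$emission$values), 1e-12)

  mixed <- generate_spectra(0.4, b, noise = 0.01, seed = 2)
  r <- unmix_absorption(mixed$absorption, b)
  expect_lt(abs(r$dimer_fraction - 0.4), 0.02)
})

test_that("distance series sits on the Hill curve at zero noise", {
  hill <- list(F_min = 0.1, F_max = 0.9, d50 = 18, h = 1)
  g <- generate_distance_series(hill, distances = c(10, 18, 26), noise = 0,
                                seed = 1)
  expect_equal(g$table$emission[2], (0.1 + 0.9) / 2)
  expect_equal(g$truth$d50, 18)
})

test_that("the paper preset encodes a self-consistent scenario", {
  cfg <- paper_preset(5)
  expect_equal(cfg$tcspc$lifetimes_ns, c(0.115, 2.2, 16.3))
  expect_equal(cfg$tcspc$amplitude_ratio, c(10000, 1000, 1))
  expect_equal(cfg$fcs$tauD_ms, 0.24)
  expect_equal(cfg$hill$d50, 18)
  # dimer fraction decreases with ruler length; 0P is almost fully dimeric
  expect_true(all(diff(cfg$constructs$dimer_fraction) < 0))

  sc <- generate_scenario(cfg, distances = c(9.7, 17.8, 21.4, 26.2))
  # the same dark fraction drives spectra and FCS amplitude per construct
  for (lab in cfg$constructs$label) {
    expect_equal(sc[[lab]]$spectra$truth$dimer_fraction,
                 sc[[lab]]$dimer_fraction)
    N <- particle_number(sc[[lab]]$fcs$truth)$N_uncorrected
    expect_equal(N, 10 * (1 - sc[[lab]]$dimer_fraction), tolerance = 1e-9)
  }
  # seeds recorded in every generated artifact
  expect_true(all(vapply(cfg$constructs$label, function(lab)
    is.integer(sc[[lab]]$decay$seed), logical(1))))
})
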