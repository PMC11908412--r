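# Shared small fixtures: 1024 x 50 ps histograms keep the unit tests quick;
# the full paper-preset acquisition is exercised in the acceptance suite.

small_irf <- gaussian_irf(1024, 50, fwhm_ps = 120)

test_that("reconvolution with a delta IRF reproduces the analytic decay", {
  delta <- instrument_response(c(1, rep(0, 1023)), 50)
  m <- multi_exp_model(c(1000, 200), c(0.5, 4))
  t <- ((1:1024) - 0.5) * 50e-3  # channel centres
  oracle <- 1000 * exp(-t / 0.5) + 200 * exp(-t / 4) + 3
  m$background <- 3
  expect_equal(reconvolve(m, delta), oracle, tolerance = 1e-10)
})

test_that("reconvolution is linear in the amplitudes", {
  m1 <- multi_exp_model(c(500, 100), c(0.4, 3), background = 7)
  m2 <- multi_exp_model(c(1000, 200), c(0.4, 3), background = 7)
  r1 <- reconvolve(m1, small_irf)
  r2 <- reconvolve(m2, small_irf)
  expect_equal(r2 - 7, 2 * (r1 - 7), tolerance = 1e-9)
})

test_that("late-time log slope of a reconvolved decay equals -1/tau", {
  irf <- gaussian_irf(2048, 25, fwhm_ps = 100)
  m <- multi_exp_model(1e5, 2.2)
  y <- reconvolve(m, irf)
  t <- ((1:2048) - 0.5) * 25e-3
  win <- t > 10 & t < 40
  slope <- coef(lm(log(y[win]) ~ t[win]))[2]
  expect_lt(abs(-1 / slope - 2.2) / 2.2, 0.005)
})

test_that("total reconvolved counts match the closed-form geometric sum", {
  m <- multi_exp_model(c(2000, 400), c(0.8, 6), background = 2)
  y <- reconvolve(m, small_irf)
  dt <- 50e-3; Tw <- 1024 * dt
  expected <- sum(m$amplitudes * (m$lifetimes_ns / dt) *
                    (1 - exp(-Tw / m$lifetimes_ns))) + 2 * 1024
  expect_lt(abs(sum(y) - expected) / expected, 0.01)
})

test_that("noiseless single-exponential decays are recovered exactly", {
  m <- multi_exp_model(5e4, 2.2)
  y <- reconvolve(m, small_irf)
  fit <- fit_decay(decay_histogram(y, 50), small_irf, 1, weighting = "neyman")
  expect_lt(abs(fit$model$lifetimes_ns - 2.2) / 2.2, 1e-3)
  expect_lt(abs(fit$model$amplitudes - 5e4) / 5e4, 1e-3)
})

test_that("Poisson three-exponential decays are recovered within 10%", {
  truth <- multi_exp_model(c(10000, 1000, 1), c(0.115, 2.2, 16.3))
  g <- generate_decay(truth, total_counts = 5e6, seed = 101)
  fit <- fit_decay(g$hist, g$irf, 3)
  expect_true(all(abs(fit$model$lifetimes_ns / g$truth$lifetimes_ns - 1) < 0.1))
  expect_output(print(fit), "tau1")
})

test_that("pure background data is flagged degenerate", {
  set.seed(33)
  y <- rpois(1024, 20)
  fit <- fit_decay(decay_histogram(y, 50), small_irf, 1, weighting = "neyman")
  expect_true(fit$degenerate)
})

test_that("global fit of one histogram matches the single fit", {
  m <- multi_exp_model(c(3000, 600), c(0.5, 4))
  g <- generate_decay(m, total_counts = 1e6, n_channels = 1024,
                      channel_width_ps = 50, seed = 7)
  single <- fit_decay(g$hist, g$irf, 2, weighting = "neyman")
  glob <- global_fit(list(g$hist), g$irf, 2, weighting = "neyman")
  expect_equal(glob$lifetimes_ns, single$model$lifetimes_ns, tolerance = 1e-4)
})

test_that("global fit shares lifetimes and is order-invariant", {
  h <- list(); irfs <- list()
  ratios <- list(c(3000, 600), c(600, 3000), c(1500, 1500))
  for (i in seq_along(ratios)) {
    g <- generate_decay(multi_exp_model(ratios[[i]], c(0.5, 4)),
                        total_counts = 1e6, n_channels = 1024,
                        channel_width_ps = 50, seed = 40 + i)
    h[[i]] <- g$hist; irfs[[i]] <- g$irf
  }
  gf <- global_fit(h, irfs[[1]], 2)
  expect_true(all(abs(gf$lifetimes_ns / c(0.5, 4) - 1) < 0.1))
  # per-curve amplitude ratios recovered
  r_hat <- vapply(gf$models, function(m) m$amplitudes[1] / m$amplitudes[2],
                  numeric(1))
  r_true <- vapply(ratios, function(a) a[1] / a[2], numeric(1))
  expect_true(all(abs(r_hat / r_true - 1) < 0.15))
  # permuting the histogram order leaves the shared lifetimes unchanged
  gf_perm <- global_fit(h[c(3, 1, 2)], irfs[[1]], 2)
  expect_equal(gf_perm$lifetimes_ns, gf$lifetimes_ns, tolerance = 5e-3)
})

test_that("component-count selection finds the true model order", {
  g1 <- generate_decay(multi_exp_model(5000, 2.2), total_counts = 2e6,
                       n_channels = 1024, channel_width_ps = 50, seed = 55)
  sel1 <- select_component_count(g1$hist, g1$irf, max_n = 3)
  expect_equal(sel1$n, 1)

  g3 <- generate_decay(multi_exp_model(c(8000, 800, 80), c(0.2, 2, 20)),
                       total_counts = 5e6, seed = 56)
  sel3 <- select_component_count(g3$hist, g3$irf, max_n = 4)
  expect_equal(sel3$n, 3)
  # the 4th component is rejected: no significant F-test improvement from 3
  expect_gt(sel3$log$p_F_next[3], 0.01)
})

test_that("amplitude fractions follow the population and intensity formulas", {
  expect_equal(fractional_populations(c(2, 2)), c(0.5, 0.5))
  p <- fractional_populations(c(10000, 1000, 1))
  expect_equal(p, c(0.90901, 0.090901, 9.09e-5), tolerance = 1e-3)
  expect_equal(sum(p), 1)
  # scale invariance
  expect_equal(fractional_populations(c(3, 7) * 1e6),
               fractional_populations(c(3, 7)))

  f_eq <- fractional_intensities(c(3, 7), c(2, 2))
  expect_equal(f_eq, fractional_populations(c(3, 7)))
  f <- fractional_intensities(c(10000, 1000, 1), c(0.115, 2.2, 16.3))
  expect_equal(f[3], 16.3 / (10000 * 0.115 + 1000 * 2.2 + 16.3),
               tolerance = 1e-12)
  expect_lt(f[3], 0.005)
  # permutation equivariance
  perm <- c(2, 3, 1)
  expect_equal(fractional_intensities(c(10, 20, 5)[perm], c(1, 2, 3)[perm]),
               fractional_intensities(c(10, 20, 5), c(1, 2, 3))[perm])
  expect_error(fractional_populations(c(0, 0)), "undefined")
  expect_error(fractional_intensities(c(1, 1), c(1, -1)))
})

test_that("global fit of identical copies returns the single-fit lifetimes", {
  m <- multi_exp_model(c(3000, 600), c(0.5, 4))
  g <- generate_decay(m, total_counts = 1e6, n_channels = 1024,
                      channel_width_ps = 50, seed = 9)
  single <- fit_decay(g$hist, g$irf, 2)
  gf <- global_fit(list(g$hist, g$hist, g$hist), g$irf, 2)
  expect_equal(gf$lifetimes_ns, single$model$lifetimes_ns, tolerance = 1e-3)
})
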