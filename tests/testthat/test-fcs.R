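test_that("FCS model limits match the closed forms", {
  m <- fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 5, T = 0.2, tauT_us = 7)
  # tau -> 0 limit: G0 / (1 - T)
  expect_equal(fcs_eval(m, 1e-18), m$G0 / (1 - m$T), tolerance = 1e-12)
  # tau -> infinity: 0
  expect_lt(fcs_eval(m, 1e4), 1e-7)
  # T = 0, tau = tauD, s -> infinity: half amplitude
  m2 <- fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 1e6, T = 0, tauT_us = 7)
  expect_equal(fcs_eval(m2, 0.24e-3), 0.05, tolerance = 1e-9)
  # monotone non-increasing on a dense grid
  g <- fcs_eval(m, 10^seq(-8, 0, length.out = 2000))
  expect_true(all(diff(g) <= 1e-15))
  expect_error(fcs_model(G0 = -1, tauD_ms = 1))
  expect_error(fcs_model(G0 = 0.1, tauD_ms = 1, T = 1))
})

test_that("noiseless curves are fit to better than 0.5%", {
  truth <- fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 5, T = 0.2, tauT_us = 7)
  cv <- correlation_curve(fcs_lag_grid(), fcs_eval(truth, fcs_lag_grid()))
  fit <- fit_fcs(cv)
  p <- coef(fit)
  expect_lt(abs(p[["G0"]] / 0.1 - 1), 0.005)
  expect_lt(abs(p[["tauD_ms"]] / 0.24 - 1), 0.005)
  expect_lt(abs(p[["T"]] / 0.2 - 1), 0.005)
  expect_lt(abs(p[["tauT_us"]] / 7 - 1), 0.005)
})

test_that("pure-diffusion data fit with a free triplet gives T ~ 0", {
  truth <- fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 5, T = 0)
  lag <- fcs_lag_grid()
  fit <- fit_fcs(correlation_curve(lag, fcs_eval(truth, lag)))
  expect_lt(coef(fit)[["T"]], 0.01)
})

test_that("fit-eval round trip holds over random parameter draws", {
  lag <- fcs_lag_grid()
  set.seed(14)
  for (i in 1:8) {
    truth <- fcs_model(G0 = runif(1, 0.02, 0.5),
                       tauD_ms = 10^runif(1, -1.2, 0.5), s = 5,
                       T = runif(1, 0.05, 0.4),
                       tauT_us = 10^runif(1, 0.3, 1.3))
    fit <- fit_fcs(correlation_curve(lag, fcs_eval(truth, lag)))
    expect_lt(abs(coef(fit)[["tauD_ms"]] / truth$tauD_ms - 1), 0.01)
    expect_lt(abs(coef(fit)[["G0"]] / truth$G0 - 1), 0.01)
  }
})

test_that("global FCS fit shares the diffusion time across curves", {
  lag <- fcs_lag_grid()
  g0s <- c(0.05, 0.1, 0.2)
  curves <- lapply(seq_along(g0s), function(i)
    generate_fcs_curve(fcs_model(g0s[i], 0.24, 5, 0.15, 7), lag, 0.02,
                       seed = 70 + i)$curve)
  gf <- global_fit_fcs(curves)
  expect_lt(abs(gf$shared[["tauD_ms"]] / 0.24 - 1), 0.05)
  fitted_g0 <- vapply(gf$models, `[[`, numeric(1), "G0")
  expect_equal(order(fitted_g0), order(g0s))
  # permutation invariance of the shared estimate
  gf2 <- global_fit_fcs(curves[c(2, 3, 1)])
  expect_equal(gf2$shared[["tauD_ms"]], gf$shared[["tauD_ms"]],
               tolerance = 1e-6)
  # single curve reduces to fit_fcs
  gf1 <- global_fit_fcs(curves[1])
  expect_equal(gf1$models[[1]]$tauD_ms,
               coef(fit_fcs(curves[[1]]))[["tauD_ms"]], tolerance = 1e-8)
})

test_that("particle number is the inverse corrected amplitude", {
  expect_equal(particle_number(fcs_model(0.1, 0.24, T = 0))$N, 10)
  pn <- particle_number(fcs_model(0.1, 0.24, T = 0.2, tauT_us = 7))
  expect_equal(pn$N, 8)
  expect_equal(pn$N_uncorrected, 10)
  # homogeneous of degree -1 in G0
  expect_equal(particle_number(fcs_model(0.05, 0.24, T = 0))$N,
               2 * particle_number(fcs_model(0.1, 0.24, T = 0))$N)
})

test_that("apparent particle number drops with the dark-dimer fraction", {
  sc_cfg <- paper_preset(3)
  # use the preset dark fractions directly; more dimer -> fewer bright helices
  dark <- sc_cfg$constructs$dimer_fraction
  Ns <- vapply(dark, function(f) {
    g <- generate_fcs_curve(fcs_model(1 / (10 * (1 - f)), 0.24, 5, 0.15, 7),
                            fcs_lag_grid(), 0.02, seed = round(100 * f))
    particle_number(fit_fcs(g$curve)$model)$N
  }, numeric(1))
  expect_true(all(diff(Ns) > 0))  # 0P -> 6P: fewer dark dimers, more particles
})

test_that("extra-relaxation detection separates null from injected dynamics", {
  truth <- fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 5, T = 0.2, tauT_us = 7)
  lag <- fcs_lag_grid()
  null_curve <- generate_fcs_curve(truth, lag, 0.02, seed = 81)$curve
  d0 <- detect_extra_relaxation(null_curve)
  expect_equal(d0$verdict, "fast-or-slow-window")
  expect_equal(d0$fast_bound_s, 100e-9)
  expect_equal(d0$slow_window_s[2], 0.3)
  expect_equal(d0$slow_window_s[1], d0$base_fit$model$tauD_ms * 1e-3)

  inj <- null_curve
  inj$G <- inj$G * (1 + 0.5 * exp(-lag / 50e-6))
  d1 <- detect_extra_relaxation(inj)
  expect_equal(d1$verdict, "detected")
  expect_lt(abs(d1$tauR_s / 50e-6 - 1), 0.25)

  # exact base-model data: the augmented model brings no significant gain
  exact <- correlation_curve(lag, fcs_eval(truth, lag))
  d2 <- detect_extra_relaxation(exact)
  expect_equal(d2$verdict, "fast-or-slow-window")
})

test_that("triplet-power trend is confirmed only for increasing T", {
  up <- data.frame(power = c(1, 2, 4), T = c(0.05, 0.15, 0.30))
  r <- triplet_power_trend(up)
  expect_equal(r$tau, 1)
  expect_equal(r$verdict, "triplet-consistent")
  flat <- data.frame(power = c(1, 2, 4, 8), T = rep(0.2, 4))
  expect_equal(triplet_power_trend(flat)$verdict, "not-confirmed")

  # noisy simulated fits at five powers confirm the trend in >= 90% of runs
  set.seed(17)
  hits <- 0
  for (i in 1:100) {
    Tt <- pmin(pmax(seq(0.05, 0.35, length.out = 5) * (1 + rnorm(5, 0, 0.1)),
                    0.001), 0.9)
    if (triplet_power_trend(data.frame(power = 1:5, T = Tt))$verdict ==
        "triplet-consistent") hits <- hits + 1
  }
  expect_gte(hits, 90)
})
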