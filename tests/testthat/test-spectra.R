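test_that("spectrum and basis constructors enforce their invariants", {
  expect_error(spectrum(c(500, 499), c(1, 1)), "increasing")
  expect_error(spectrum(c(500, 510), c(1, NA)))
  b <- spectral_basis()
  expect_equal(b$monomer$wavelengths[which.max(b$monomer$values)], 550)
  expect_equal(b$dimer$wavelengths[which.max(b$dimer$values)], 520)
  expect_true(all(b$monomer$values >= 0) && all(b$dimer$values >= 0))
})

test_that("unmixing recovers constructed mixture fractions", {
  b <- spectral_basis()
  # pure monomer
  r <- unmix_absorption(b$monomer, b)
  expect_equal(r$monomer_fraction, 1, tolerance = 1e-9)
  expect_equal(r$dimer_fraction, 0, tolerance = 1e-9)
  # exact convex combinations over a grid of weights
  for (f in c(0.1, 0.25, 0.5, 0.8)) {
    mix <- spectrum(b$monomer$wavelengths,
                    (1 - f) * b$monomer$values + f * b$dimer$values)
    r <- unmix_absorption(mix, b)
    expect_equal(r$dimer_fraction, f, tolerance = 1e-6)
    expect_lt(r$residual, 1e-8)
  }
})

test_that("unmixing fractions are physical and inputs validated", {
  b <- spectral_basis()
  set.seed(21)
  for (i in 1:10) {
    v <- pmax(b$monomer$values * runif(1, 0, 2) -
                b$dimer$values * runif(1, 0, 0.5), 0) + runif(1, 0, 0.1)
    r <- unmix_absorption(spectrum(b$monomer$wavelengths, v), b)
    expect_gte(r$monomer_fraction, 0)
    expect_gte(r$dimer_fraction, 0)
    expect_equal(r$monomer_fraction + r$dimer_fraction, 1)
  }
  expect_error(unmix_absorption(
    spectrum(b$monomer$wavelengths, rep(0, length(b$monomer$wavelengths))), b),
    "undefined")
})

test_that("unmixing resamples spectra on mismatched wavelength grids", {
  b <- spectral_basis()
  wl <- seq(455, 645, by = 2.5)
  mix <- spectrum(wl, approx(b$monomer$wavelengths,
                             0.6 * b$monomer$values + 0.4 * b$dimer$values,
                             xout = wl)$y)
  r <- unmix_absorption(mix, b)
  expect_equal(r$dimer_fraction, 0.4, tolerance = 1e-3)
})

test_that("band shift converts wavelengths to wavenumbers with H/J sign", {
  expect_equal(band_shift_wavenumbers(550, 520), 1e7 / 520 - 1e7 / 550)
  expect_equal(band_shift_wavenumbers(550, 520), 1048.95, tolerance = 0.01)
  expect_equal(band_shift_wavenumbers(550, 550), 0)
  # antisymmetric under swapping the two bands
  expect_equal(band_shift_wavenumbers(520, 550),
               -band_shift_wavenumbers(550, 520))
})

test_that("exciton coupling follows the point-dipole law", {
  expect_equal(exciton_splitting(5, 10, kappa = 0)$coupling_cm1, 0)
  v1 <- exciton_splitting(5, 10, kappa = 1)
  v2 <- exciton_splitting(5, 20, kappa = 1)
  expect_equal(v1$coupling_cm1 / v2$coupling_cm1, 8)      # R^-3
  vk <- exciton_splitting(5, 10, kappa = 0.37)
  expect_equal(vk$coupling_cm1, 0.37 * v1$coupling_cm1)   # kappa-linear
  expect_equal(v1$type, "H")  # cofacial parallel dipoles: blue-shifted band
  expect_equal(exciton_splitting(5, 10, kappa = -1)$type, "J")
  expect_error(exciton_splitting(5, 0, 1))
})

test_that("monomer similarity separates monomer from dimer spectra", {
  b <- spectral_basis()
  expect_equal(monomer_similarity(b$monomer, b), 1.0, tolerance = 1e-12)
  expect_lt(monomer_similarity(b$dimer, b), 0.98)
  # invariant to positive scaling
  sc <- spectrum(b$monomer$wavelengths, 37 * b$monomer$values)
  expect_equal(monomer_similarity(sc, b), 1.0, tolerance = 1e-12)
  expect_error(monomer_similarity(
    spectrum(b$monomer$wavelengths, rep(0, length(b$monomer$values))), b),
    "zero-norm")
})

test_that("FRET distance/efficiency conversions invert each other", {
  expect_equal(fret_distance_from_efficiency(0.5, 40), 40)
  expect_equal(fret_distance_from_efficiency(0.9, 50), 34.67, tolerance = 0.01)
  for (E in c(0.05, 0.3, 0.7, 0.99)) {
    R <- fret_distance_from_efficiency(E, 50)
    expect_equal(fret_efficiency_from_distance(R, 50), E, tolerance = 1e-10)
  }
  expect_error(fret_distance_from_efficiency(1, 50))
  expect_error(fret_distance_from_efficiency(0, 50))
})
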