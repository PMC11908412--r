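# Synthetic-data generators with embedded ground truth. Every generator is
# deterministic under its seed and returns the true parameters alongside the
# data, so recovery tests never hard-code expected values. Noise models:
# Poisson for photon-counting histograms, multiplicative Gaussian with a
# lag-dependent scale for correlation curves, additive Gaussian for spectra.

# Independent per-purpose seed streams derived from one master seed, so that
# adding a generator never shifts another generator's stream.
derive_seed <- function(master, purpose) {
  offsets <- c(decay = 101, fcs = 211, blink = 307, spectra = 401,
               distance = 503, misc = 601)
  stopifnot(purpose %in% names(offsets))
  as.integer((as.numeric(master) * 7919 + offsets[[purpose]]) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Paper-preset study conditions
#'
#' The construct series and model parameters the synthetic generators default
#' to: three decay components at 0.115/2.2/16.3 ns with amplitude ratio
#' 10000:1000:1, an FCS model with a 0.24 ms diffusion time and 7 us triplet
#' lifetime, the 18 Angstrom Hill midpoint with coefficient 1, and the
#' 0P/3P/5P/6P ruler series with dimer (dark) fractions decreasing with
#' length. The same per-construct dark fraction feeds both the spectral
#' mixtures and the FCS particle numbers so the scenario is self-consistent.
#'
#' @param seed Master seed; per-generator streams are derived from it.
#' @return A list of class `scenario_config`.
#' @export
paper_preset <- function(seed = 1L) {
  constructs <- data.frame(
    label = c("0P", "3P", "5P", "6P"),
    n_pro = c(0, 3, 5, 6),
    dimer_fraction = c(0.95, 0.55, 0.15, 0.05))
  structure(list(
    constructs = constructs,
    tcspc = list(
      lifetimes_ns = c(0.115, 2.2, 16.3),
      amplitude_ratio = c(10000, 1000, 1),
      n_channels = 4096, channel_width_ps = 25,
      irf_fwhm_ps = 120, total_counts = 5e6),
    fcs = list(
      tauD_ms = 0.24, tauT_us = 7, s = 5, G0 = 0.1, T = 0.15,
      noise = 0.02, lag_grid = fcs_lag_grid(5e-8, 1, 8)),
    spectra = list(basis = spectral_basis(), emission_peak_nm = 575,
                   emission_width_nm = 20, noise = 0.01),
    hill = list(F_min = 0, F_max = 1, d50 = 18, h = 1),
    seed = as.integer(seed)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario: ", paste(x$constructs$label, collapse = "/"),
      sprintf(" | lifetimes %s ns | tauD %g ms | d50 %g A | seed %d\n",
              paste(x$tcspc$lifetimes_ns, collapse = "/"),
              x$fcs$tauD_ms, x$hill$d50, x$seed))
  invisible(x)
}

#' Generate a Poisson-noised TCSPC decay with its IRF
#'
#' The expected curve is [reconvolve()] of the model with a Gaussian IRF,
#' scaled so the expectation totals `total_counts`; each channel then draws
#' an independent Poisson count. The true model (after scaling) and seed are
#' embedded in the result.
#'
#' @param model A [multi_exp_model()]; amplitudes set the component ratio,
#'   the overall scale comes from `total_counts`.
#' @param total_counts Requested expected total (>= 1000).
#' @param n_channels,channel_width_ps,irf_fwhm_ps Acquisition settings.
#' @param label Construct label stored on the histogram.
#' @param seed RNG seed.
#' @return List with `hist` ([decay_histogram()]), `irf`
#'   ([instrument_response()]), `truth` (scaled [multi_exp_model()]) and
#'   `seed`.
#' @export
generate_decay <- function(model, total_counts = 5e6, n_channels = 4096,
                           channel_width_ps = 25, irf_fwhm_ps = 120,
                           label = "", seed = 1L) {
  stopifnot(inherits(model, "multi_exp_model"), total_counts >= 1e3)
  irf <- gaussian_irf(n_channels, channel_width_ps, irf_fwhm_ps)
  mu0 <- reconvolve(model, irf, n_channels)
  sc <- total_counts / sum(mu0)
  truth <- multi_exp_model(model$amplitudes * sc, model$lifetimes_ns,
                           model$shift_ps, model$background * sc)
  mu <- mu0 * sc
  counts <- with_seed(seed, rpois(n_channels, mu))
  list(hist = decay_histogram(counts, channel_width_ps, label), irf = irf,
       truth = truth, seed = seed)
}

#' Generate a noisy FCS correlation curve
#'
#' `G = fcs_eval(model) * (1 + eps)` with `eps ~ N(0, noise * w(tau))` and a
#' weight `w` increasing log-linearly from 0.5 at the shortest lag to 2 at
#' the longest, mimicking the poorer statistics of long-lag correlator
#' channels.
#'
#' @param model An [fcs_model()].
#' @param lags_s Lag grid (s).
#' @param noise Relative noise scale at mid-grid (>= 0).
#' @param power Optional laser power label.
#' @param seed RNG seed.
#' @return List with `curve` ([correlation_curve()]), `truth`, `seed`.
#' @export
generate_fcs_curve <- function(model, lags_s = fcs_lag_grid(), noise = 0.02,
                               power = NA_real_, seed = 1L) {
  stopifnot(inherits(model, "fcs_model"), noise >= 0)
  g <- fcs_eval(model, lags_s)
  u <- if (length(lags_s) > 1)
    (log(lags_s) - log(min(lags_s))) / (log(max(lags_s)) - log(min(lags_s)))
  else 0.5
  w <- 0.5 * 4^u
  eps <- with_seed(seed, rnorm(length(g), 0, noise * w))
  curve <- correlation_curve(lags_s, g * (1 + eps),
                             stderr = if (noise > 0) pmax(abs(g) * noise * w, 1e-12),
                             power = power)
  list(curve = curve, truth = model, seed = seed)
}

#' Generate a blinking (telegraph) intensity trace
#'
#' Sum of `n_particles` independent two-state emitters switching on with
#' rate `k_on` and off with rate `k_off` (1/s), each emitting
#' `brightness` expected counts per second while on; per-bin counts are
#' Poisson. The stationary on-probability is `k_on / (k_on + k_off)` and the
#' intensity autocorrelation decays with rate `k_on + k_off`, which is what
#' the correlator stack is validated against.
#'
#' @param n_particles Number of emitters.
#' @param k_on,k_off Switching rates (1/s).
#' @param brightness Expected counts per second while on.
#' @param duration_s Trace length (s).
#' @param bin_width_s Bin width (s).
#' @param seed RNG seed.
#' @return List with `intensity` (counts per bin), `bin_width_s`, `truth`
#'   (list of the generator parameters) and `seed`.
#' @export
generate_blinking_trace <- function(n_particles = 10, k_on = 500, k_off = 500,
                                    brightness = 5e4, duration_s = 1,
                                    bin_width_s = 1e-4, seed = 1L) {
  stopifnot(k_on > 0, k_off > 0, duration_s > 0, bin_width_s > 0,
            duration_s > 10 / (k_on + k_off))
  n_bins <- floor(duration_s / bin_width_s)
  p_on <- k_on / (k_on + k_off)
  mu <- with_seed(seed, {
    total_on <- numeric(n_bins)  # fraction of each bin spent "on", summed
    edges <- seq_len(n_bins + 1)
    for (p in seq_len(n_particles)) {
      state <- runif(1) < p_on
      t <- 0
      on_frac <- numeric(n_bins)
      while (t < duration_s) {
        dwell <- rexp(1, if (state) k_off else k_on)
        t2 <- min(t + dwell, duration_s)
        if (state) {
          # accumulate overlap of [t, t2) with each bin
          b1 <- floor(t / bin_width_s) + 1
          b2 <- min(floor((t2 - 1e-15) / bin_width_s) + 1, n_bins)
          for (b in b1:b2) {
            lo <- max(t, (b - 1) * bin_width_s)
            hi <- min(t2, b * bin_width_s)
            on_frac[b] <- on_frac[b] + (hi - lo) / bin_width_s
          }
        }
        t <- t2
        state <- !state
      }
      total_on <- total_on + on_frac
    }
    total_on * brightness * bin_width_s
  })
  counts <- with_seed(seed + 1L, rpois(n_bins, mu))
  list(intensity = counts, bin_width_s = bin_width_s,
       truth = list(n_particles = n_particles, k_on = k_on, k_off = k_off,
                    brightness = brightness, p_on = p_on,
                    relaxation_rate = k_on + k_off),
       seed = seed)
}

#' Generate a construct's absorption, excitation and emission spectra
#'
#' Absorption is the dimer-fraction mixture of the basis spectra; under the
#' exciton interpretation the dimer is dark, so excitation follows the
#' monomer basis and emission the monomer emission band (Gaussian at
#' 575 nm), both scaled by the monomer fraction. Gaussian noise is added to
#' all three.
#'
#' @param dimer_fraction Fraction of dye in dimers, in `[0, 1]`.
#' @param basis A [spectral_basis()].
#' @param emission_peak_nm,emission_width_nm Emission band parameters.
#' @param noise Additive Gaussian noise sd, as a fraction of each spectrum's
#'   maximum.
#' @param seed RNG seed.
#' @return List with `absorption`, `excitation`, `emission` ([spectrum()]s),
#'   `truth`, `seed`.
#' @export
generate_spectra <- function(dimer_fraction, basis = spectral_basis(),
                             emission_peak_nm = 575, emission_width_nm = 20,
                             noise = 0.01, seed = 1L) {
  stopifnot(dimer_fraction >= 0, dimer_fraction <= 1, noise >= 0)
  wl <- basis$monomer$wavelengths
  mono <- 1 - dimer_fraction
  absv <- mono * basis$monomer$values + dimer_fraction * basis$dimer$values
  excv <- mono * basis$monomer$values
  wl_em <- seq(540, 700, by = 1)
  emv <- mono * gaussian_band(wl_em, emission_peak_nm, emission_width_nm, 1)
  noised <- with_seed(seed, {
    list(a = absv + rnorm(length(absv), 0, noise * max(absv)),
         x = excv + rnorm(length(excv), 0, noise * max(absv)),
         e = emv + rnorm(length(emv), 0, noise * max(1, max(emv))))
  })
  list(absorption = spectrum(wl, noised$a, "absorption"),
       excitation = spectrum(wl, noised$x, "excitation"),
       emission = spectrum(wl_em, noised$e, "emission"),
       truth = list(dimer_fraction = dimer_fraction,
                    monomer_fraction = mono),
       seed = seed)
}

#' Generate a fluorescence-versus-distance calibration table
#'
#' Hill curve plus additive Gaussian noise. By default the distances are the
#' four ruler mean dye separations computed by the geometry pipeline
#' (n = 0, 3, 5, 6); pass `distances` explicitly to avoid recomputing them.
#'
#' @param hill List with `F_min`, `F_max`, `d50`, `h`.
#' @param distances Distances (A); default runs [ruler_distances()].
#' @param noise Gaussian noise sd as a fraction of `F_max`.
#' @param seed RNG seed.
#' @return List with `table` (data frame `distance`, `emission`), `truth`,
#'   `seed`.
#' @export
generate_distance_series <- function(hill = list(F_min = 0, F_max = 1,
                                                 d50 = 18, h = 1),
                                     distances = NULL, noise = 0.05,
                                     seed = 1L) {
  if (is.null(distances)) distances <- ruler_distances()$distance
  stopifnot(all(distances > 0), noise >= 0)
  f <- hill$F_min + (hill$F_max - hill$F_min) * distances^hill$h /
    (hill$d50^hill$h + distances^hill$h)
  y <- f + with_seed(seed, rnorm(length(f), 0, noise * hill$F_max))
  list(table = data.frame(distance = distances, emission = y),
       truth = hill, seed = seed)
}

#' Generate the full paper-preset scenario
#'
#' One call producing, for each construct in the preset: TCSPC decay +
#' IRF, FCS curve (with particle number reduced according to the dark
#' dimer fraction), and the spectra set; plus the shared distance-response
#' table. Used by the command-line `simulate` subcommand and by end-to-end
#' tests.
#'
#' @param config A `scenario_config` from [paper_preset()].
#' @param distances Optional ruler distances (A) to avoid recomputation.
#' @return Nested list keyed by construct label plus `distance_series`,
#'   `config`.
#' @export
generate_scenario <- function(config = paper_preset(), distances = NULL) {
  sd0 <- config$seed
  cons <- config$constructs
  if (is.null(distances)) distances <- ruler_distances(cons$n_pro)$distance
  out <- list()
  for (i in seq_len(nrow(cons))) {
    lab <- cons$label[i]
    dark <- cons$dimer_fraction[i]
    amp <- config$tcspc$amplitude_ratio
    dec <- generate_decay(
      multi_exp_model(amp, config$tcspc$lifetimes_ns),
      total_counts = config$tcspc$total_counts,
      n_channels = config$tcspc$n_channels,
      channel_width_ps = config$tcspc$channel_width_ps,
      irf_fwhm_ps = config$tcspc$irf_fwhm_ps,
      label = lab, seed = derive_seed(sd0 + i, "decay"))
    # dark dimers lower the apparent particle number -> larger G0
    N_eff <- (1 - dark) / config$fcs$G0
    fmod <- fcs_model(G0 = 1 / max(N_eff, 1e-6), tauD_ms = config$fcs$tauD_ms,
                      s = config$fcs$s, T = config$fcs$T,
                      tauT_us = config$fcs$tauT_us)
    fc <- generate_fcs_curve(fmod, config$fcs$lag_grid, config$fcs$noise,
                             seed = derive_seed(sd0 + i, "fcs"))
    sp <- generate_spectra(dark, config$spectra$basis,
                           config$spectra$emission_peak_nm,
                           config$spectra$emission_width_nm,
                           config$spectra$noise,
                           seed = derive_seed(sd0 + i, "spectra"))
    out[[lab]] <- list(decay = dec, fcs = fc, spectra = sp,
                       dimer_fraction = dark, n_pro = cons$n_pro[i],
                       distance = distances[i])
  }
  out$distance_series <- generate_distance_series(
    config$hill, distances = distances,
    noise = 0.05, seed = derive_seed(sd0, "distance"))
  out$config <- config
  out
}
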