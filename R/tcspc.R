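# TCSPC reconvolution analysis. The measured decay is the convolution of the
# instrument response function (IRF) with a multi-exponential impulse
# response, plus a constant background. Fitting uses variable projection:
# the nonlinear search runs over lifetimes and the IRF sub-channel shift
# only, while amplitudes and background (in which the model is linear) are
# solved by non-negative least squares at every step.

#' Construct a TCSPC decay histogram
#'
#' @param counts Non-negative integer photon counts per channel (>= 64
#'   channels).
#' @param channel_width_ps Channel width (ps).
#' @param label Optional construct label.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, channel_width_ps, label = "") {
  stopifnot(length(counts) >= 64, all(counts >= 0), all(is.finite(counts)),
            channel_width_ps > 0)
  structure(list(counts = as.numeric(counts),
                 channel_width_ps = channel_width_ps, label = label),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay histogram%s: %d channels x %.1f ps, %.3g counts\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$counts), x$channel_width_ps, sum(x$counts)))
  invisible(x)
}

#' Construct an instrument response function
#'
#' Values are normalised to unit area; the IRF must share the channel axis of
#' the decays it is used with.
#'
#' @param values Non-negative IRF values per channel.
#' @param channel_width_ps Channel width (ps).
#' @return An object of class `instrument_response`.
#' @export
instrument_response <- function(values, channel_width_ps) {
  stopifnot(all(values >= 0), sum(values) > 0, channel_width_ps > 0)
  structure(list(values = as.numeric(values) / sum(values),
                 channel_width_ps = channel_width_ps),
            class = "instrument_response")
}

#' Gaussian instrument response on a channel grid
#'
#' @param n_channels Number of channels.
#' @param channel_width_ps Channel width (ps).
#' @param fwhm_ps Full width at half maximum (ps).
#' @param t0_ps Peak position (ps).
#' @return An [instrument_response()].
#' @export
gaussian_irf <- function(n_channels, channel_width_ps, fwhm_ps = 120,
                         t0_ps = 10 * channel_width_ps) {
  t <- (seq_len(n_channels) - 1) * channel_width_ps
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  instrument_response(exp(-0.5 * ((t - t0_ps) / sigma)^2), channel_width_ps)
}

#' Construct a multi-exponential decay model
#'
#' @param amplitudes Non-negative amplitudes (counts at t = 0 per component).
#' @param lifetimes_ns Component lifetimes (ns), reported sorted ascending.
#' @param shift_ps IRF time shift (ps).
#' @param background Constant background (counts/channel).
#' @return An object of class `multi_exp_model`.
#' @export
multi_exp_model <- function(amplitudes, lifetimes_ns, shift_ps = 0,
                            background = 0) {
  stopifnot(length(amplitudes) == length(lifetimes_ns),
            all(amplitudes >= 0), all(is.finite(amplitudes)),
            all(lifetimes_ns > 0), background >= 0)
  ord <- order(lifetimes_ns, -amplitudes)
  structure(list(amplitudes = amplitudes[ord],
                 lifetimes_ns = lifetimes_ns[ord],
                 shift_ps = shift_ps, background = background),
            class = "multi_exp_model")
}

#' @export
print.multi_exp_model <- function(x, ...) {
  cat("multi-exponential decay model\n")
  for (i in seq_along(x$amplitudes))
    cat(sprintf("  a%d = %.4g, tau%d = %.4g ns\n", i, x$amplitudes[i],
                i, x$lifetimes_ns[i]))
  cat(sprintf("  shift = %.1f ps, background = %.3g counts/channel\n",
              x$shift_ps, x$background))
  invisible(x)
}

# FFT linear convolution of each column of `basis` with the (shifted) IRF.
# Sub-channel shifts are applied to the IRF as a Fourier phase ramp.
convolve_irf <- function(basis, irf_values, shift_channels = 0) {
  n <- nrow(basis)
  npad <- 2^ceiling(log2(2 * n))
  irf_pad <- c(irf_values, rep(0, npad - n))
  H <- fft(irf_pad)
  if (shift_channels != 0) {
    k <- c(0:(npad / 2), -(npad / 2 - 1):-1)
    H <- H * exp(-2i * pi * k * shift_channels / npad)
  }
  out <- matrix(0, n, ncol(basis))
  for (j in seq_len(ncol(basis))) {
    col_pad <- c(basis[, j], rep(0, npad - n))
    conv <- Re(fft(fft(col_pad) * H, inverse = TRUE)) / npad
    out[, j] <- conv[seq_len(n)]
  }
  out
}

#' Reconvolve a decay model with an instrument response
#'
#' Expected counts per channel: the discrete convolution of the
#' multi-exponential impulse response with the unit-area (optionally
#' time-shifted) IRF, plus the constant background. Linear in the
#' amplitudes. With a delta-function IRF in channel 1 the output is the pure
#' multi-exponential sampled at the channel grid.
#'
#' @param model A [multi_exp_model()].
#' @param irf An [instrument_response()].
#' @param n_channels Number of output channels (default: length of the IRF).
#' @return Numeric vector of expected counts per channel.
#' @export
reconvolve <- function(model, irf, n_channels = length(irf$values)) {
  stopifnot(inherits(model, "multi_exp_model"),
            inherits(irf, "instrument_response"))
  dt_ns <- irf$channel_width_ps / 1000
  t <- (seq_len(n_channels) - 0.5) * dt_ns  # channel centres
  basis <- vapply(model$lifetimes_ns, function(tau) exp(-t / tau),
                  numeric(n_channels))
  conv <- convolve_irf(basis, irf$values[seq_len(n_channels)],
                       model$shift_ps / irf$channel_width_ps)
  as.numeric(conv %*% model$amplitudes + model$background)
}

# Lawson-Hanson style non-negative least squares for small column counts.
nnls_small <- function(A, y, max_iter = 10 * ncol(A)) {
  p <- ncol(A)
  passive <- rep(FALSE, p)
  beta <- numeric(p)
  for (iter in seq_len(max_iter)) {
    w <- crossprod(A, y - A %*% beta)  # gradient
    w[passive] <- -Inf
    if (all(w <= 1e-10 * max(1, sum(abs(y))))) break
    passive[which.max(w)] <- TRUE
    repeat {
      bp <- qr.coef(qr(A[, passive, drop = FALSE]), y)
      bp[is.na(bp)] <- 0
      if (all(bp >= 0)) {
        beta[] <- 0; beta[passive] <- bp
        break
      }
      full <- numeric(p); full[passive] <- bp
      neg <- passive & full < 0
      alpha <- min(beta[neg] / (beta[neg] - full[neg]))
      beta <- beta + alpha * (full - beta)
      passive <- passive & beta > 1e-12
    }
  }
  beta
}

# Variable-projection residual for one or more histograms sharing lifetimes.
# theta = c(log(tau_ns), shift per curve); returns weighted residuals and,
# as attributes, the solved linear parameters.
varpro_residuals <- function(theta, hists, irfs, n_comp, weighting) {
  taus <- exp(theta[seq_len(n_comp)])
  shifts <- theta[-seq_len(n_comp)]
  res <- vector("list", length(hists))
  amps <- matrix(0, length(hists), n_comp)
  bgs <- numeric(length(hists))
  for (c in seq_along(hists)) {
    y <- hists[[c]]$counts
    n <- length(y)
    dt_ns <- hists[[c]]$channel_width_ps / 1000
    t <- (seq_len(n) - 0.5) * dt_ns
    basis <- vapply(taus, function(tau) exp(-t / tau), numeric(n))
    conv <- convolve_irf(basis, irfs[[c]]$values[seq_len(n)], shifts[c])
    X <- cbind(conv, 1)
    w <- 1 / sqrt(pmax(y, 1))  # Neyman weights with unit floor
    beta <- nnls_small(X * w, y * w)
    amps[c, ] <- beta[seq_len(n_comp)]
    bgs[c] <- beta[n_comp + 1]
    res[[c]] <- (y - X %*% beta) * w
  }
  out <- unlist(res)
  attr(out, "amplitudes") <- amps
  attr(out, "backgrounds") <- bgs
  out
}

# deterministic multi-start initial lifetime sets (ns)
start_lifetimes <- function(n_comp, dt_ns, window_ns, n_starts) {
  base <- exp(seq(log(2 * dt_ns), log(window_ns / 2), length.out = max(n_comp, 2)))
  base <- base[seq_len(n_comp)]
  scales <- c(1, 0.4, 2.5, 0.15, 6)[seq_len(n_starts)]
  lapply(scales, function(s) pmin(pmax(base * s, dt_ns / 2), window_ns * 2))
}

fit_decay_core <- function(hists, irfs, n_components, n_starts = 3,
                           extra_starts = NULL) {
  dt_ns <- hists[[1]]$channel_width_ps / 1000
  window_ns <- length(hists[[1]]$counts) * dt_ns
  starts <- start_lifetimes(n_components, dt_ns, window_ns, n_starts)
  if (!is.null(extra_starts)) starts <- c(extra_starts, starts)
  nc <- length(hists)
  best <- NULL
  for (st in starts) {
    theta0 <- c(log(st), rep(0, nc))
    fit <- try(minpack.lm::nls.lm(
      par = theta0, fn = varpro_residuals,
      lower = c(rep(log(dt_ns / 20), n_components), rep(-10, nc)),
      upper = c(rep(log(window_ns * 10), n_components), rep(10, nc)),
      hists = hists, irfs = irfs, n_comp = n_components,
      weighting = "neyman",
      control = minpack.lm::nls.lm.control(maxiter = 120, ptol = 1e-10)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("decay fit failed to converge from any start")
  r <- varpro_residuals(best$par, hists, irfs, n_components, "neyman")
  taus <- exp(best$par[seq_len(n_components)])
  shifts <- best$par[-seq_len(n_components)]
  amps <- attr(r, "amplitudes")
  bgs <- attr(r, "backgrounds")
  # lifetime standard errors from the outer Gauss-Newton approximation
  npar_tot <- n_components * (1 + nc) + 2 * nc
  dof <- length(r) - npar_tot
  se_tau <- rep(NA_real_, n_components)
  cv <- try(solve(best$hessian), silent = TRUE)
  if (!inherits(cv, "try-error") && dof > 0) {
    sc <- best$deviance / dof
    se_log <- sqrt(pmax(diag(cv)[seq_len(n_components)], 0) * sc)
    se_tau <- taus * se_log
  }
  ord <- order(taus)
  list(lifetimes_ns = taus[ord], se_lifetimes = se_tau[ord],
       amplitudes = amps[, ord, drop = FALSE], backgrounds = bgs,
       shifts_channels = shifts, deviance = best$deviance, dof = dof,
       converged = best$info %in% 1:4)
}

#' Fit a multi-exponential decay by IRF reconvolution
#'
#' Minimises the Poisson-weighted (Neyman) chi-square, with weights
#' `1/max(counts, 1)`, over amplitudes, lifetimes, IRF shift and constant
#' background. Amplitudes and background are constrained non-negative and
#' solved by non-negative least squares at each step of the nonlinear search
#' over lifetimes and shift (variable projection); the search is repeated
#' from several deterministic log-spaced lifetime starts. Optionally the
#' Neyman solution is refined by direct minimisation of the Poisson deviance
#' (`weighting = "mle"`).
#'
#' @param hist A [decay_histogram()].
#' @param irf An [instrument_response()] on the same channel axis.
#' @param n_components Number of exponential components (1 to 4).
#' @param weighting `"mle"` (default) or `"neyman"`. The Neyman chi-square
#'   estimator biases lifetimes of components that live in low-count
#'   channels (the classic `1/max(y,1)` weight pathology), so by default its
#'   solution is refined by direct Poisson maximum likelihood.
#' @param n_starts Number of deterministic multi-starts.
#' @return An object of class `decay_fit` with the fitted
#'   [multi_exp_model()] in `$model`, `se_lifetimes`, `chisq_reduced`,
#'   `converged` and diagnostics.
#' @export
fit_decay <- function(hist, irf, n_components = 3,
                      weighting = c("mle", "neyman"), n_starts = 3) {
  weighting <- match.arg(weighting)
  stopifnot(n_components >= 1, n_components <= 4)
  core <- fit_decay_core(list(hist), list(irf), n_components, n_starts)
  model <- multi_exp_model(core$amplitudes[1, ], core$lifetimes_ns,
                           core$shifts_channels[1] * hist$channel_width_ps,
                           core$backgrounds[1])
  if (weighting == "mle") {
    refined <- refine_mle(list(model), list(hist), list(irf))
    model <- refined$models[[1]]
    core$lifetimes_ns <- model$lifetimes_ns
    core$amplitudes[1, ] <- model$amplitudes
    core$backgrounds[1] <- model$background
    core$deviance <- sum((hist$counts -
                            reconvolve(model, irf, length(hist$counts)))^2 /
                           pmax(hist$counts, 1))
  }
  degenerate <- sum(model$amplitudes) * max(model$lifetimes_ns) <
    0.01 * sum(hist$counts) * hist$channel_width_ps / 1000
  structure(list(model = model, se_lifetimes = core$se_lifetimes,
                 chisq_reduced = core$deviance / core$dof,
                 deviance = core$deviance, dof = core$dof,
                 n_components = n_components, weighting = weighting,
                 converged = core$converged, degenerate = degenerate,
                 hist = hist, irf = irf),
            class = "decay_fit")
}

poisson_deviance <- function(mu, y) {
  mu <- pmax(mu, 1e-12)
  2 * sum(ifelse(y > 0, y * log(y / mu) - (y - mu), mu))
}

# Joint Poisson maximum-likelihood refinement with lifetimes shared across
# histograms; per-histogram amplitudes, shift and background stay free.
refine_mle <- function(models, hists, irfs) {
  k <- length(models[[1]]$lifetimes_ns)
  nc <- length(hists)
  pack <- c(log(models[[1]]$lifetimes_ns),
            unlist(lapply(models, function(m)
              c(log(m$amplitudes + 1e-12), m$shift_ps,
                log(m$background + 1e-6)))))
  unpack <- function(p) {
    taus <- exp(p[seq_len(k)])
    lapply(seq_len(nc), function(c) {
      off <- k + (c - 1) * (k + 2)
      multi_exp_model(exp(p[off + seq_len(k)]), taus,
                      p[off + k + 1], exp(p[off + k + 2]))
    })
  }
  obj <- function(p) {
    ms <- unpack(p)
    sum(vapply(seq_len(nc), function(c)
      poisson_deviance(reconvolve(ms[[c]], irfs[[c]],
                                  length(hists[[c]]$counts)),
                       hists[[c]]$counts), numeric(1)))
  }
  opt <- nlminb(pack, obj, control = list(iter.max = 300, eval.max = 600))
  list(models = unpack(opt$par), deviance = opt$objective)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%d-exponential reconvolution fit (%s weighting), chi2_red = %.3f\n",
              x$n_components, x$weighting, x$chisq_reduced))
  m <- x$model
  for (i in seq_along(m$amplitudes))
    cat(sprintf("  tau%d = %.4g ns (se %.2g), a%d = %.4g\n", i,
                m$lifetimes_ns[i], x$se_lifetimes[i], i, m$amplitudes[i]))
  cat(sprintf("  shift = %.2f ps, background = %.3g\n", m$shift_ps,
              m$background))
  if (x$degenerate) cat("  note: flagged degenerate (signal ~ background)\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  m <- object$model
  c(setNames(m$lifetimes_ns, paste0("tau", seq_along(m$lifetimes_ns))),
    setNames(m$amplitudes, paste0("a", seq_along(m$amplitudes))),
    shift_ps = m$shift_ps, background = m$background)
}

#' @export
fitted.decay_fit <- function(object, ...) {
  reconvolve(object$model, object$irf, length(object$hist$counts))
}

#' @export
residuals.decay_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  y <- object$hist$counts
  r <- y - fitted(object)
  if (type == "weighted") r / sqrt(pmax(y, 1)) else r
}

#' Global multi-exponential fit with shared lifetimes
#'
#' Fits several decay histograms simultaneously with one shared lifetime set
#' and free per-histogram amplitudes, IRF shifts and backgrounds — the
#' standard way to stabilise lifetime estimates across a construct series
#' when the species are common but their populations differ.
#'
#' @param histograms List of [decay_histogram()]s.
#' @param irf A single [instrument_response()] or a list, one per histogram.
#' @param n_components Number of shared exponential components.
#' @param weighting `"mle"` (default) or `"neyman"`; see [fit_decay()].
#' @param n_starts Number of deterministic multi-starts.
#' @return An object of class `global_decay_fit`: shared `lifetimes_ns` and
#'   `se_lifetimes`, per-histogram `models` (list of [multi_exp_model()]),
#'   per-histogram and global reduced chi-squares.
#' @export
global_fit <- function(histograms, irf, n_components = 3,
                       weighting = c("mle", "neyman"), n_starts = 3) {
  weighting <- match.arg(weighting)
  stopifnot(length(histograms) >= 1)
  irfs <- if (inherits(irf, "instrument_response"))
    rep(list(irf), length(histograms)) else irf
  stopifnot(length(irfs) == length(histograms))
  core <- fit_decay_core(histograms, irfs, n_components, n_starts)
  models <- lapply(seq_along(histograms), function(c)
    multi_exp_model(core$amplitudes[c, ], core$lifetimes_ns,
                    core$shifts_channels[c] * histograms[[c]]$channel_width_ps,
                    core$backgrounds[c]))
  if (weighting == "mle") {
    refined <- refine_mle(models, histograms, irfs)
    models <- refined$models
    core$lifetimes_ns <- models[[1]]$lifetimes_ns
    core$deviance <- sum(vapply(seq_along(histograms), function(c) {
      y <- histograms[[c]]$counts
      sum((y - reconvolve(models[[c]], irfs[[c]], length(y)))^2 /
            pmax(y, 1))
    }, numeric(1)))
  }
  # per-histogram reduced chi-square
  per <- vapply(seq_along(histograms), function(c) {
    y <- histograms[[c]]$counts
    f <- reconvolve(models[[c]], irfs[[c]], length(y))
    sum((y - f)^2 / pmax(y, 1)) / (length(y) - (2 * n_components + 2))
  }, numeric(1))
  structure(list(lifetimes_ns = core$lifetimes_ns,
                 se_lifetimes = core$se_lifetimes, models = models,
                 chisq_reduced = core$deviance / core$dof,
                 chisq_per_histogram = per,
                 labels = vapply(histograms, `[[`, character(1), "label"),
                 converged = core$converged,
                 histograms = histograms, irfs = irfs),
            class = "global_decay_fit")
}

#' @export
print.global_decay_fit <- function(x, ...) {
  cat(sprintf("global reconvolution fit: %d histograms, shared lifetimes, chi2_red = %.3f\n",
              length(x$models), x$chisq_reduced))
  cat("  shared lifetimes (ns):",
      paste(sprintf("%.4g (se %.2g)", x$lifetimes_ns, x$se_lifetimes),
            collapse = ", "), "\n")
  for (c in seq_along(x$models)) {
    lab <- if (nzchar(x$labels[c])) x$labels[c] else paste0("curve ", c)
    cat(sprintf("  %s: amplitudes %s, chi2_red %.3f\n", lab,
                paste(sprintf("%.4g", x$models[[c]]$amplitudes), collapse = ", "),
                x$chisq_per_histogram[c]))
  }
  invisible(x)
}

#' @export
coef.global_decay_fit <- function(object, ...) {
  setNames(object$lifetimes_ns,
           paste0("tau", seq_along(object$lifetimes_ns)))
}

#' Choose the number of exponential components
#'
#' Fits 1 to `max_n` components and returns the smallest order for which (a)
#' adding one more component gives no significant F-test improvement at
#' level `alpha`, and (b) the weighted-residual lag-1 autocorrelation is
#' below `acf_threshold`. Both criteria are reported per order in `$log`.
#' The comparison uses the Neyman least-squares fits, for which the nested
#' F-test on chi-square is the natural framework.
#'
#' @param hist A [decay_histogram()].
#' @param irf An [instrument_response()].
#' @param max_n Maximum model order tried.
#' @param alpha F-test significance level.
#' @param acf_threshold Maximum acceptable lag-1 autocorrelation of the
#'   weighted residuals.
#' @return List with `n` (chosen order), `log` (data frame of per-order
#'   diagnostics) and `fits` (the underlying `decay_fit` objects).
#' @export
select_component_count <- function(hist, irf, max_n = 4, alpha = 0.01,
                                   acf_threshold = 0.1) {
  stopifnot(max_n >= 1)
  fits <- vector("list", max_n)
  warm <- NULL
  for (n in seq_len(max_n)) {
    core <- fit_decay_core(list(hist), list(irf), n, n_starts = 3,
                           extra_starts = warm)
    fits[[n]] <- core
    # warm-start the next order from this solution plus one longer component
    warm <- list(c(core$lifetimes_ns,
                   min(max(core$lifetimes_ns) * 4,
                       length(hist$counts) * hist$channel_width_ps / 1000)))
  }
  nchan <- length(hist$counts)
  acf1 <- vapply(seq_len(max_n), function(n) {
    m <- multi_exp_model(fits[[n]]$amplitudes[1, ], fits[[n]]$lifetimes_ns,
                         fits[[n]]$shifts_channels[1] * hist$channel_width_ps,
                         fits[[n]]$backgrounds[1])
    r <- (hist$counts - reconvolve(m, irf, nchan)) / sqrt(pmax(hist$counts, 1))
    r1 <- r[-1]; r0 <- r[-length(r)]
    sum((r1 - mean(r)) * (r0 - mean(r))) / sum((r - mean(r))^2)
  }, numeric(1))
  p_next <- rep(NA_real_, max_n)
  for (n in seq_len(max_n - 1)) {
    rss1 <- fits[[n]]$deviance; rss2 <- fits[[n + 1]]$deviance
    df2 <- fits[[n + 1]]$dof
    dp <- 2  # one extra amplitude + lifetime pair
    # the unit weight floor deflates the residual variance in empty tail
    # channels (chi2_red < 1 there), while the gain from an extra component
    # is concentrated in well-populated channels with unit-variance
    # residuals; the denominator scale is therefore floored at 1
    Fstat <- max(0, (rss1 - rss2) / dp / max(rss2 / df2, 1))
    p_next[n] <- pf(Fstat, dp, df2, lower.tail = FALSE)
  }
  ok <- vapply(seq_len(max_n), function(n) {
    improves <- if (n < max_n) p_next[n] < alpha else FALSE
    !improves && abs(acf1[n]) < acf_threshold
  }, logical(1))
  chosen <- if (any(ok)) which(ok)[1] else max_n
  list(n = chosen,
       log = data.frame(n = seq_len(max_n),
                        chisq = vapply(fits, function(f) f$deviance / f$dof,
                                       numeric(1)),
                        p_F_next = p_next, acf_lag1 = acf1, adequate = ok),
       fits = fits)
}

#' Fractional populations from decay amplitudes
#'
#' Number share of molecules in each decay environment, `p_i = a_i / sum(a)`,
#' assuming equal radiative rates across components.
#'
#' @param amplitudes Non-negative amplitudes, not all zero.
#' @return Fractions summing to 1.
#' @export
fractional_populations <- function(amplitudes) {
  stopifnot(all(amplitudes >= 0))
  s <- sum(amplitudes)
  if (s == 0) stop("all-zero amplitudes: fractions undefined")
  amplitudes / s
}

#' Fractional steady-state intensities from amplitudes and lifetimes
#'
#' Photon share of each decay component, `f_i = a_i tau_i / sum(a tau)`. With
#' the amplitude ratio ~10000:1000:1 and lifetimes 0.115/2.2/16.3 ns this
#' gives the slowest phase under half a percent of the collected light.
#'
#' @param amplitudes Non-negative amplitudes, not all zero.
#' @param lifetimes Positive lifetimes, same length.
#' @return Fractions summing to 1.
#' @export
fractional_intensities <- function(amplitudes, lifetimes) {
  stopifnot(length(amplitudes) == length(lifetimes),
            all(amplitudes >= 0), all(lifetimes > 0))
  s <- sum(amplitudes * lifetimes)
  if (s == 0) stop("all-zero amplitudes: fractions undefined")
  amplitudes * lifetimes / s
}
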