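# Multiple-tau software correlator. Short lags are correlated at the native
# bin width; after every octave (m lags) the trace is re-binned by a factor
# of two, so the lag grid is quasi-logarithmic and the cost stays O(N log N)
# while still reaching second-long lags from nanosecond bins.

#' Multiple-tau autocorrelation of an intensity trace
#'
#' Computes the normalised fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` on a multiple-tau lag grid: the
#' first `2m` lags at the native bin width, then `m` lags per octave with
#' the trace re-binned by two at each octave boundary. The symmetric
#' normalisation (means of the two truncated segments) is used at every lag.
#'
#' @param intensity Photon counts (or intensity) per bin.
#' @param bin_width_s Bin width (s).
#' @param m Points per octave.
#' @return A [correlation_curve()].
#' @export
multiple_tau_autocorrelate <- function(intensity, bin_width_s, m = 8) {
  x <- as.numeric(intensity)
  stopifnot(length(x) >= 2 * m, bin_width_s > 0, m >= 1)
  if (mean(x) <= 0) stop("zero-mean trace: correlation undefined")

  lags_s <- numeric(0)
  G <- numeric(0)
  level_x <- x
  level_dt <- bin_width_s
  level_lag0 <- 0L          # lag (in current bins) already covered
  first <- TRUE
  repeat {
    k_set <- if (first) seq_len(2L * m) else (m + 1L):(2L * m)
    for (k in k_set) {
      if (k >= length(level_x)) break
      n <- length(level_x)
      a <- level_x[1:(n - k)]
      b <- level_x[(k + 1):n]
      ma <- mean(a); mb <- mean(b)
      if (ma <= 0 || mb <= 0) next
      lags_s <- c(lags_s, k * level_dt)
      G <- c(G, mean(a * b) / (ma * mb) - 1)
    }
    # rebin by two for the next octave
    n2 <- floor(length(level_x) / 2)
    if (n2 < 2 * m || (2L * m) * level_dt * 2 > length(x) * bin_width_s / 2)
      break
    level_x <- level_x[seq_len(2 * n2)]
    level_x <- level_x[c(TRUE, FALSE)] + level_x[c(FALSE, TRUE)]
    level_dt <- level_dt * 2
    first <- FALSE
    if (max(lags_s) >= length(x) * bin_width_s / 4) break
  }
  ord <- order(lags_s)
  correlation_curve(lags_s[ord], G[ord])
}

#' Brute-force autocorrelation at given lags
#'
#' Direct O(N * n_lags) evaluation of the symmetric-normalised fluctuation
#' autocorrelation at integer-bin lags. Exact but slow; the reference the
#' multiple-tau correlator is validated against.
#'
#' @param intensity Counts per bin.
#' @param bin_width_s Bin width (s).
#' @param lag_bins Integer vector of lags in bins.
#' @return A [correlation_curve()].
#' @export
brute_force_autocorrelate <- function(intensity, bin_width_s, lag_bins) {
  x <- as.numeric(intensity)
  stopifnot(all(lag_bins >= 1), all(lag_bins < length(x)))
  if (mean(x) <= 0) stop("zero-mean trace: correlation undefined")
  G <- vapply(lag_bins, function(k) {
    n <- length(x)
    a <- x[1:(n - k)]; b <- x[(k + 1):n]
    mean(a * b) / (mean(a) * mean(b)) - 1
  }, numeric(1))
  correlation_curve(lag_bins * bin_width_s, G)
}
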