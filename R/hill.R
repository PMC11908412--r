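# Hill-form fluorescence-versus-distance calibration. Fluorescence recovers
# with increasing inter-dye distance as dimers can no longer form; the
# response is modelled as F(d) = F_min + (F_max - F_min) d^h / (d50^h + d^h)
# with the Hill coefficient fixed at 1 by default.

#' Fit the Hill distance-response calibration
#'
#' Least-squares fit of emission intensity against mean dye separation with
#' the saturation form `F(d) = F_min + (F_max - F_min) d^h / (d50^h + d^h)`.
#' `d50` is the calibration midpoint: the distance at which half of the
#' quenchable fluorescence is recovered. The Hill coefficient `h` is fixed
#' (default 1) rather than fitted; it is exposed for sensitivity checks only.
#'
#' @param points Data frame (or list of pairs) with columns `distance`
#'   (Angstrom, > 0) and `emission` (a.u.); at least 3 points.
#' @param h Fixed Hill coefficient.
#' @param fix Optional named list fixing `F_min` and/or `F_max` instead of
#'   fitting them, e.g. `list(F_min = 0, F_max = 1)` for emission already
#'   normalised to the unquenched monomer signal. With only four ruler
#'   constructs the three-parameter fit is poorly determined under noise;
#'   fixing the asymptotes makes the midpoint identifiable.
#' @return An object of class `hill_fit` with components `coefficients`
#'   (`F_min`, `F_max`, `d50`), `se` (asymptotic standard errors), `h`,
#'   `fitted`, `residuals`, `converged` and `data`.
#' @examples
#' d <- c(9.7, 17.8, 21.4, 26.2)
#' f <- 0 + 1 * d / (18 + d)
#' fit <- fit_hill_distance_response(data.frame(distance = d, emission = f))
#' coef(fit)["d50"]
#' @export
fit_hill_distance_response <- function(points, h = 1, fix = list()) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(distance = p[[1]], emission = p[[2]])))
  }
  stopifnot(all(c("distance", "emission") %in% names(points)),
            nrow(points) >= 3, all(points$distance > 0), h > 0)
  d <- points$distance; y <- points$emission
  if (sd(y) == 0 || all(!is.finite(y)))
    stop("degenerate (constant) emission data: fit cannot converge")

  stopifnot(all(names(fix) %in% c("F_min", "F_max")))
  all_names <- c("F_min", "F_max", "d50")
  start <- c(F_min = min(y), F_max = max(y), d50 = median(d))
  start[names(fix)] <- unlist(fix)
  free <- setdiff(all_names, names(fix))
  model <- function(p, d) p["F_min"] + (p["F_max"] - p["F_min"]) * d^h /
    (p["d50"]^h + d^h)
  expand <- function(th) { p <- start; p[free] <- th; p }
  res_fn <- function(th) y - model(expand(th), d)
  lower <- setNames(c(-Inf, -Inf, 1e-6), all_names)
  fit <- minpack.lm::nls.lm(par = start[free], fn = res_fn,
                            lower = lower[free],
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- expand(fit$par)
  converged <- fit$info %in% 1:4
  # asymptotic standard errors from the Jacobian at the solution
  se <- setNames(rep(NA_real_, 3), all_names)
  dof <- length(y) - length(free)
  if (dof > 0) {
    cv <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    if (!inherits(cv, "try-error")) se[free] <- sqrt(pmax(diag(cv), 0))
  }
  se[names(fix)] <- 0
  structure(list(coefficients = p, se = se, h = h,
                 fitted = model(p, d), residuals = y - model(p, d),
                 deviance = fit$deviance, converged = converged,
                 data = data.frame(distance = d, emission = y)),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill distance-response fit (h = %g)\n", x$h))
  cat(sprintf("  d50   = %.2f A (se %.2f)\n", x$coefficients["d50"], x$se["d50"]))
  cat(sprintf("  F_min = %.4g, F_max = %.4g\n",
              x$coefficients["F_min"], x$coefficients["F_max"]))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, se = object$se)
  cat(sprintf("Hill distance-response fit (h = %g), RSS = %.4g, %s\n",
              object$h, object$deviance,
              if (object$converged) "converged" else "NOT converged"))
  print(out)
  invisible(out)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$distance else
    if (is.data.frame(newdata)) newdata$distance else newdata
  p <- object$coefficients; h <- object$h
  p["F_min"] + (p["F_max"] - p["F_min"]) * d^h / (p["d50"]^h + d^h)
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$data$distance, x$data$emission, xlab = "mean dye separation (A)",
       ylab = "emission (a.u.)", ...)
  dd <- seq(min(x$data$distance) * 0.5, max(x$data$distance) * 1.2, length.out = 200)
  lines(dd, predict(x, dd))
  abline(v = x$coefficients["d50"], lty = 2)
}
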