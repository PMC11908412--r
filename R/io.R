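# CSV and report I/O. All tabular formats are comma-separated with a header
# row; column names are matched case-insensitively against a synonym table.
# Reports and manifests are flat key = value text files.

.column_synonyms <- list(
  wavelength_nm = c("wavelength_nm", "wavelength", "lambda", "lambda_nm", "wl"),
  value = c("value", "absorbance", "abs", "intensity", "counts", "signal",
            "fluorescence", "emission"),
  time_ps = c("time_ps", "t_ps", "time", "channel_time"),
  counts = c("counts", "count", "photons"),
  lag_s = c("lag_s", "lag", "tau", "tau_s", "lagtime"),
  g = c("g", "g_tau", "correlation", "autocorrelation"),
  stderr = c("stderr", "se", "sd", "error", "sigma"),
  distance = c("distance", "distance_a", "d", "r", "separation"),
  emission = c("emission", "f", "fluorescence", "intensity", "value"),
  time_s = c("time_s", "t_s", "t", "time")
)

match_column <- function(header, canonical) {
  syn <- .column_synonyms[[canonical]]
  hit <- which(tolower(header) %in% syn)
  if (length(hit) == 0)
    stop(sprintf("missing required column '%s' (accepted names: %s)",
                 canonical, paste(syn, collapse = ", ")), call. = FALSE)
  hit[1]
}

#' Read a typed two/three-column CSV table
#'
#' Header names are matched case-insensitively against a synonym table; the
#' axis column (wavelength, time or lag) must be strictly increasing and all
#' cells numeric. Failures are distinct, messageful errors.
#'
#' @param path CSV file path.
#' @param schema Character vector of canonical column names, in order; names
#'   prefixed with `?` are optional (e.g. `"?stderr"`).
#' @param monotone Canonical name of the column required to be strictly
#'   increasing, or `NULL`.
#' @return Data frame with canonical column names.
#' @export
read_table <- function(path, schema, monotone = schema[1]) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- list()
  for (col in schema) {
    optional <- startsWith(col, "?")
    canonical <- sub("^\\?", "", col)
    idx <- tryCatch(match_column(names(raw), canonical),
                    error = function(e) if (optional) NA_integer_ else stop(e))
    if (is.na(idx)) next
    v <- raw[[idx]]
    vn <- suppressWarnings(as.numeric(v))
    if (anyNA(vn))
      stop(sprintf("non-numeric cell(s) in column '%s' of %s",
                   names(raw)[idx], path), call. = FALSE)
    out[[canonical]] <- vn
  }
  out <- as.data.frame(out)
  if (!is.null(monotone) && monotone %in% names(out) &&
      any(diff(out[[monotone]]) <= 0))
    stop(sprintf("column '%s' in %s must be strictly increasing",
                 monotone, path), call. = FALSE)
  out
}

#' Read a spectrum from CSV
#'
#' @param path Two-column CSV (wavelength_nm, value).
#' @param kind Spectrum kind.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = "absorption") {
  d <- read_table(path, c("wavelength_nm", "value"))
  spectrum(d$wavelength_nm, d$value, kind)
}

#' Write a spectrum to CSV
#' @param sp A [spectrum()].
#' @param path Output path.
#' @export
write_spectrum_csv <- function(sp, path) {
  write.csv(data.frame(wavelength_nm = sp$wavelengths, value = sp$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a TCSPC decay (or IRF) from CSV
#'
#' @param path Two-column CSV (time_ps, counts); channel width inferred from
#'   the time axis (must be uniform).
#' @param label Construct label.
#' @return A [decay_histogram()].
#' @export
read_decay_csv <- function(path, label = "") {
  d <- read_table(path, c("time_ps", "counts"))
  dt <- diff(d$time_ps)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop(sprintf("non-uniform channel axis in %s", path), call. = FALSE)
  decay_histogram(d$counts, dt[1], label)
}

#' Write a decay histogram to CSV
#' @param hist A [decay_histogram()] or [instrument_response()].
#' @param path Output path.
#' @export
write_decay_csv <- function(hist, path) {
  v <- if (inherits(hist, "instrument_response")) hist$values else hist$counts
  write.csv(data.frame(
    time_ps = (seq_along(v) - 1) * hist$channel_width_ps, counts = v),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a correlation curve from CSV
#'
#' @param path CSV with columns (lag_s, g) and optionally stderr.
#' @param power Laser power label.
#' @return A [correlation_curve()].
#' @export
read_curve_csv <- function(path, power = NA_real_) {
  d <- read_table(path, c("lag_s", "g", "?stderr"))
  correlation_curve(d$lag_s, d$g, stderr = d[["stderr"]], power = power)
}

#' Write a correlation curve to CSV
#' @param curve A [correlation_curve()].
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  d <- data.frame(lag_s = curve$lags_s, g = curve$G)
  if (!is.null(curve$stderr)) d$stderr <- curve$stderr
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

flatten_report <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flatten_report(v, key))
    else out <- c(out, paste0(key, " = ",
                              paste(format(v, digits = 15), collapse = ", ")))
  }
  out
}

#' Write a structured key-value report
#'
#' Serialises a fit result (or any nested list of numeric/character scalars
#' and vectors) as machine-parseable `key = value` lines, prefixed with the
#' tool version and any seed found in the object.
#'
#' @param result Named (possibly nested) list; `decay_fit`, `fcs_fit`,
#'   `hill_fit` and `global_decay_fit` objects are summarised automatically.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  payload <- report_payload(result)
  lines <- c(paste0("tool = quenchcal ",
                    as.character(packageVersion("quenchcal"))),
             flatten_report(payload))
  writeLines(lines, path)
  invisible(path)
}

report_payload <- function(result) {
  if (inherits(result, "decay_fit")) {
    m <- result$model
    list(type = "decay_fit", n_components = result$n_components,
         lifetimes_ns = m$lifetimes_ns, amplitudes = m$amplitudes,
         shift_ps = m$shift_ps, background = m$background,
         se_lifetimes = result$se_lifetimes,
         chisq_reduced = result$chisq_reduced,
         converged = result$converged,
         fractional_populations = fractional_populations(m$amplitudes),
         fractional_intensities = fractional_intensities(m$amplitudes,
                                                         m$lifetimes_ns))
  } else if (inherits(result, "global_decay_fit")) {
    c(list(type = "global_decay_fit", lifetimes_ns = result$lifetimes_ns,
           se_lifetimes = result$se_lifetimes,
           chisq_reduced = result$chisq_reduced),
      setNames(lapply(seq_along(result$models), function(i) {
        m <- result$models[[i]]
        list(amplitudes = m$amplitudes,
             fractional_populations = fractional_populations(m$amplitudes),
             fractional_intensities = fractional_intensities(m$amplitudes,
                                                             m$lifetimes_ns),
             background = m$background,
             chisq_reduced = result$chisq_per_histogram[i])
      }), ifelse(nzchar(result$labels), result$labels,
                 paste0("curve", seq_along(result$models)))))
  } else if (inherits(result, "fcs_fit")) {
    list(type = "fcs_fit", G0 = result$model$G0,
         tauD_ms = result$model$tauD_ms, s = result$model$s,
         T = result$model$T, tauT_us = result$model$tauT_us,
         se = as.list(result$se), chisq_reduced = result$chisq_reduced,
         N = particle_number(result$model)$N,
         converged = result$converged)
  } else if (inherits(result, "hill_fit")) {
    list(type = "hill_fit", F_min = result$coefficients[["F_min"]],
         F_max = result$coefficients[["F_max"]],
         d50 = result$coefficients[["d50"]], h = result$h,
         se = as.list(as.list(result$se)), converged = result$converged)
  } else if (is.list(result)) {
    result
  } else stop("unsupported result type")
}

#' Read a key-value report written by [write_report()]
#'
#' @param path Report path.
#' @return Named list; dotted keys become nested lists, numeric values are
#'   parsed as numeric vectors.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    v <- if (!anyNA(num)) num else if (all(vals %in% c("TRUE", "FALSE")))
      as.logical(vals) else vals
    keys <- strsplit(trimws(kv[1]), ".", fixed = TRUE)[[1]]
    out <- assign_nested(out, keys, v)
  }
  out
}

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
  } else {
    if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
    lst[[keys[1]]] <- assign_nested(lst[[keys[1]]], keys[-1], value)
  }
  lst
}
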