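#' Configuration for rolling-window early-warning-signal detection
#'
#' The detector slides a fixed-length window over the nNSD series and
#' computes, per window, the sample standard deviation and the lag-1
#' autocorrelation. Each indicator series is standardized (mean 0, sd 1)
#' and the composite signal strength is `|f(sd)| + |f(acf)|`. A window is a
#' warning when the strength exceeds `threshold`; `k_consecutive` warnings
#' in a row form an early warning signal (EWS).
#'
#' The defaults encode a 5-day window at a 12 h sampling interval (10
#' points), a threshold of 3.92 (the two-sided 2-sigma criterion applied to
#' each standardized indicator, 1.96 + 1.96), and a persistence of 4
#' consecutive warnings (48 h). At a 6 h interval the same 48 h persistence
#' corresponds to 8 consecutive warnings; use
#' [consecutive_windows_for_duration()] to convert.
#'
#' @param window_days window length in days (default 5).
#' @param interval_hours nominal sampling interval in hours (default 12).
#' @param window_points number of fixes per window; computed as
#'   `window_days * 24 / interval_hours` when `NULL`. Must be >= 4.
#' @param threshold warning threshold on the composite signal strength.
#' @param k_consecutive number of consecutive warning windows that
#'   constitute an EWS (default 4; the alternatives 3 and 5 are also used
#'   for summaries).
#' @param standardization_scope `"full_series"` standardizes each indicator
#'   over all windows of the series (retrospective analysis);
#'   `"expanding"` standardizes each window over the windows seen so far
#'   (prospective, real-time use).
#' @param variance_mode if `TRUE` the dispersion indicator is the sample
#'   variance instead of the standard deviation. The composite strength is
#'   invariant to monotone rescaling only through the standardization, so
#'   this switch can change which windows warn; the default (`FALSE`,
#'   standard deviation) is the conventional early-warning indicator.
#' @return A list of class `dew_ews_config`.
#' @export
ews_config <- function(window_days = 5, interval_hours = 12,
                       window_points = NULL, threshold = 3.92,
                       k_consecutive = 4,
                       standardization_scope = c("full_series", "expanding"),
                       variance_mode = FALSE) {
  if (is.null(window_points))
    window_points <- as.integer(round(window_days * 24 / interval_hours))
  standardization_scope <- match.arg(standardization_scope)
  stopifnot(window_points >= 4, k_consecutive >= 1, threshold > 0,
            interval_hours > 0)
  structure(list(window_days = window_days,
                 interval_hours = interval_hours,
                 window_points = as.integer(window_points),
                 threshold = threshold,
                 k_consecutive = as.integer(k_consecutive),
                 acf_lag = 1L,
                 standardization_scope = standardization_scope,
                 variance_mode = variance_mode),
            class = "dew_ews_config")
}

#' @rdname ews_config
#' @param k number of consecutive warning windows.
#' @return `persistence_hours()`: the duration in hours spanned by `k`
#'   consecutive warnings at the given sampling interval.
#' @export
persistence_hours <- function(k, interval_hours = 12) k * interval_hours

#' @rdname ews_config
#' @param duration_hours persistence duration to preserve, in hours.
#' @return `consecutive_windows_for_duration()`: the number of consecutive
#'   warnings spanning `duration_hours` at the given interval.
#' @export
consecutive_windows_for_duration <- function(duration_hours, interval_hours) {
  k <- duration_hours / interval_hours
  stopifnot(abs(k - round(k)) < 1e-9)
  as.integer(round(k))
}

#' Per-window dispersion and autocorrelation indicators
#'
#' `window_sd()` is the sample standard deviation (denominator `n - 1`) of
#' a window of nNSD values, in km. `window_acf1()` is the lag-1
#' autocorrelation: the window-mean-centered lag-1 autocovariance divided
#' by the window's sum of squared deviations (the standard sample acf
#' estimator, equal to `stats::acf(..., lag.max = 1)`). Both are undefined
#' (`NA`) for a constant window.
#'
#' @param values numeric vector, one rolling window of nNSD values.
#' @param variance_mode if `TRUE`, return the sample variance rather than
#'   its square root (see [ews_config()]).
#' @return A single numeric value, or `NA_real_` for a zero-variance window.
#' @examples
#' window_sd(c(rep(0, 9), 2))   # 0.6325 km
#' window_acf1(1:10)            # 0.7
#' @export
window_sd <- function(values, variance_mode = FALSE) {
  n <- length(values)
  stopifnot(n >= 2)
  v <- sum((values - mean(values))^2) / (n - 1)
  if (v <= 0) return(NA_real_)
  if (variance_mode) v else sqrt(v)
}

#' @rdname window_sd
#' @export
window_acf1 <- function(values) {
  n <- length(values)
  stopifnot(n >= 3)
  mu <- mean(values)
  d <- values - mu
  den <- sum(d^2)
  if (den <= 0) return(NA_real_)
  sum(d[-n] * d[-1]) / den
}

#' Rolling-window indicator series with composite signal strength
#'
#' Slides a window of `cfg$window_points` fixes one fix at a time over the
#' nNSD series; there are `n - window_points + 1` windows, and window `i`
#' spans data points `i` to `i + window_points - 1` (windows are indexed by
#' their first data point). Raw per-window sd and lag-1 acf are
#' standardized to mean 0 and sd 1 over the scope set in `cfg`; the signal
#' strength is `|f_sd| + |f_acf|` and a window warns when the strength
#' exceeds `cfg$threshold`. Zero-variance windows have undefined indicators:
#' they never warn and are excluded from the standardization statistics.
#'
#' @param ds a displacement series from [nsd()] (forward or reversed).
#' @param cfg an [ews_config()].
#' @return A data frame of class `dew_indicators` with columns
#'   `window_index`, `first`, `last` (data-point span), `sd_raw`, `acf_raw`,
#'   `f_sd`, `f_acf`, `strength`, `warning`.
#' @export
indicator_series <- function(ds, cfg = ews_config()) {
  z <- ds$nnsd
  n <- length(z)
  w <- cfg$window_points
  if (n < w + cfg$k_consecutive)
    stop(sprintf("series too short for detection: %d points, need >= %d",
                 n, w + cfg$k_consecutive), call. = FALSE)
  nw <- n - w + 1L
  sd_raw <- acf_raw <- numeric(nw)
  for (i in seq_len(nw)) {
    seg <- z[i:(i + w - 1L)]
    sd_raw[i] <- window_sd(seg, variance_mode = cfg$variance_mode)
    acf_raw[i] <- window_acf1(seg)
  }
  f_sd <- standardize_scope(sd_raw, cfg$standardization_scope)
  f_acf <- standardize_scope(acf_raw, cfg$standardization_scope)
  strength <- abs(f_sd) + abs(f_acf)
  warning <- !is.na(strength) & strength > cfg$threshold
  out <- data.frame(window_index = seq_len(nw), first = seq_len(nw),
                    last = seq_len(nw) + w - 1L,
                    sd_raw = sd_raw, acf_raw = acf_raw,
                    f_sd = f_sd, f_acf = f_acf,
                    strength = strength, warning = warning)
  attr(out, "cfg") <- cfg
  attr(out, "n_points") <- n
  attr(out, "id") <- attr(ds, "id")
  attr(out, "reversed") <- isTRUE(attr(ds, "reversed"))
  class(out) <- c("dew_indicators", "data.frame")
  out
}

# Standardize a raw indicator series to mean 0, sd 1 over the given scope,
# ignoring NA (zero-variance) windows.
standardize_scope <- function(x, scope) {
  if (scope == "full_series") {
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0) return(rep(NA_real_, length(x)))
    (x - m) / s
  } else {
    out <- rep(NA_real_, length(x))
    for (i in seq_along(x)) {
      xi <- x[seq_len(i)]
      s <- stats::sd(xi, na.rm = TRUE)
      if (is.na(x[i]) || !is.finite(s) || s <= 0) next
      out[i] <- (x[i] - mean(xi, na.rm = TRUE)) / s
    }
    out
  }
}

#' Detect an early warning signal as a persistence run
#'
#' Scans the warning flags for the first run of at least `cfg$k_consecutive`
#' consecutive warning windows. The EWS window index is the index of the
#' k-th window of that run; the reported span is the data-point span of the
#' run's *first* window, and the EWS time is `window index x sampling
#' interval` in hours. Only the first qualifying run is reported (one
#' transition per individual); all windows remain available for inspection.
#'
#' @param indicators a `dew_indicators` data frame from [indicator_series()].
#' @param cfg an [ews_config()].
#' @param direction `"forward"` or `"reverse"`, a label carried through to
#'   the result.
#' @return A list of class `dew_ews_detection` with elements `direction`,
#'   `detected`, `ews_window_index`, `first_run_span` (length-2 integer),
#'   `ews_time_hours`, `k`, and `windows` (the indicator data frame).
#' @examples
#' ds <- structure(
#'   data.frame(t = Sys.time() + 43200 * (1:30), nsd = 0,
#'              nnsd = c(rep(0.1, 12), seq(0.1, 8, length.out = 6),
#'                       rep(8, 12)) + sin(1:30) * 0.02),
#'   class = c("dew_displacement", "data.frame"))
#' det <- detect_ews(indicator_series(ds, ews_config()), ews_config())
#' det$detected
#' @export
detect_ews <- function(indicators, cfg = ews_config(),
                       direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  w <- indicators$warning
  k <- cfg$k_consecutive
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  out <- list(direction = direction, detected = length(hit) > 0,
              ews_window_index = NA_integer_,
              first_run_span = c(NA_integer_, NA_integer_),
              ews_time_hours = NA_real_, k = k, windows = indicators)
  if (out$detected) {
    s <- starts[hit[1]]
    out$ews_window_index <- indicators$window_index[s + k - 1L]
    out$first_run_span <- c(indicators$first[s], indicators$last[s])
    out$ews_time_hours <- out$ews_window_index * cfg$interval_hours
  }
  class(out) <- "dew_ews_detection"
  out
}

#' @export
print.dew_ews_detection <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("EWS (%s): %s, %g h\n", x$direction, format_ews_timing(x),
                x$ews_time_hours))
  } else {
    cat(sprintf("EWS (%s): none (k = %d)\n", x$direction, x$k))
  }
  invisible(x)
}

#' Format EWS timing in table notation
#'
#' Renders a detection as `"<k-th window index> [<first>-<last>]"`, where
#' the bracketed range is the data-point span of the first window of the
#' warning run, e.g. `"51 [48-57]"`.
#'
#' @param det a detection from [detect_ews()].
#' @return A character scalar, or `NA` when nothing was detected.
#' @export
format_ews_timing <- function(det) {
  if (!det$detected) return(NA_character_)
  sprintf("%d [%d-%d]", det$ews_window_index,
          det$first_run_span[1], det$first_run_span[2])
}

#' Bidirectional EWS detection on a displacement series
#'
#' Runs the rolling-window detector on the nNSD series (locating the onset
#' of the transient phase, S1 to T) and on the time-reversed series
#' (locating its end, T to S2). Reverse-pass indices are mapped back to
#' forward data-point positions by mirroring: reversed index `j`
#' corresponds to forward position `n - j + 1`. A candidate dispersal
#' transition exists only when both directions detect.
#'
#' @param ds a forward displacement series from [nsd()].
#' @param cfg an [ews_config()].
#' @return A list of class `dew_ews_bidirectional` with elements `forward`
#'   and `reverse` (each a `dew_ews_detection`); the reverse detection
#'   additionally carries `mapped_forward_index` and
#'   `mapped_forward_time_hours`, and the list carries `both_detected` and
#'   `transient_span_hours` (mapped reverse time minus forward time).
#' @export
detect_bidirectional <- function(ds, cfg = ews_config()) {
  n <- nrow(ds)
  fwd <- detect_ews(indicator_series(ds, cfg), cfg, "forward")
  rev_ds <- reverse_series(ds)
  rev <- detect_ews(indicator_series(rev_ds, cfg), cfg, "reverse")
  if (rev$detected) {
    rev$mapped_forward_index <- n - rev$ews_window_index + 1L
    rev$mapped_forward_time_hours <- rev$mapped_forward_index * cfg$interval_hours
  } else {
    rev$mapped_forward_index <- NA_integer_
    rev$mapped_forward_time_hours <- NA_real_
  }
  out <- list(forward = fwd, reverse = rev,
              both_detected = fwd$detected && rev$detected,
              transient_span_hours =
                if (fwd$detected && rev$detected)
                  rev$mapped_forward_time_hours - fwd$ews_time_hours
                else NA_real_)
  class(out) <- "dew_ews_bidirectional"
  out
}

#' Write a rolling-window indicator table to TSV
#'
#' @param indicators a `dew_indicators` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, path) {
  utils::write.table(as.data.frame(indicators), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
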