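#' Construct a telemetry track
#'
#' A track is a data frame with one row per GPS fix, holding the individual's
#' id, a timestamp, and projected coordinates in meters. Fixes are sorted by
#' time; duplicate timestamps keep the first fix only.
#'
#' @param id individual label (length-1 character).
#' @param t timestamps, `POSIXct` or numeric seconds since epoch.
#' @param x,y easting / northing in meters (projected coordinates).
#' @param crs_note free-text note on the projection the coordinates are in.
#' @return An object of class `dew_track`: a data frame with columns `t`,
#'   `x`, `y` and attributes `id` and `crs_note`.
#' @examples
#' tr <- track("f1", as.POSIXct("2021-01-01", tz = "UTC") + 3600 * c(0, 12, 24),
#'             x = c(0, 100, 250), y = c(0, -50, 30))
#' nrow(tr)
#' @export
track <- function(id, t, x, y, crs_note = "projected meters") {
  stopifnot(length(id) == 1, length(t) == length(x), length(x) == length(y))
  if (!inherits(t, "POSIXct")) t <- as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
  ok <- is.finite(x) & is.finite(y) & !is.na(t)
  t <- t[ok]; x <- x[ok]; y <- y[ok]
  o <- order(t)
  t <- t[o]; x <- x[o]; y <- y[o]
  dup <- duplicated(t)
  if (any(dup)) {
    t <- t[!dup]; x <- x[!dup]; y <- y[!dup]
  }
  if (length(t) < 2) stop_degenerate(id, length(t))
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "id") <- as.character(id)
  attr(out, "crs_note") <- crs_note
  class(out) <- c("dew_track", "data.frame")
  out
}

#' @export
print.dew_track <- function(x, ...) {
  cat(sprintf("<%s> id=%s, %d fixes, %s to %s\n",
              if (inherits(x, "dew_regular_track")) "regular track" else "track",
              track_id(x), nrow(x), format(x$t[1]), format(x$t[nrow(x)])))
  if (inherits(x, "dew_regular_track")) {
    cat(sprintf("  nominal interval %g h (tol %g h), regular fraction %.3f\n",
                attr(x, "interval_hours"), attr(x, "tolerance_hours"),
                attr(x, "regular_fraction")))
  }
  invisible(x)
}

#' @rdname track
#' @param tr a track.
#' @export
track_id <- function(tr) attr(tr, "id")

#' Read tracks from a delimited text file
#'
#' Reads a CSV/TSV of GPS fixes (one row per fix) and splits it into one
#' track per individual. Rows with missing or unparseable id, timestamp or
#' coordinates are dropped and counted; duplicate timestamps within an
#' individual keep the first fix.
#'
#' @param path file path to a delimited text file.
#' @param column_map named character vector mapping the roles `id`,
#'   `timestamp`, `x`, `y` to column names in the file. Movebank-style files
#'   can be read with e.g. `c(id = "individual-local-identifier",
#'   timestamp = "timestamp", x = "utm-easting", y = "utm-northing")`.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @param tz timezone for timestamp parsing (default `"UTC"`).
#' @return A named list of [track()] objects, one per individual, with an
#'   attribute `n_dropped` giving the number of discarded rows.
#' @export
read_tracks <- function(path,
                        column_map = c(id = "id", timestamp = "timestamp",
                                       x = "x", y = "y"),
                        sep = ",", tz = "UTC") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("input file is empty: ", path, call. = FALSE)
  need <- c("id", "timestamp", "x", "y")
  if (!all(need %in% names(column_map)))
    stop("column_map must name id, timestamp, x and y", call. = FALSE)
  missing_cols <- setdiff(unname(column_map[need]), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  id <- as.character(df[[column_map[["id"]]]])
  tt <- df[[column_map[["timestamp"]]]]
  t <- if (inherits(tt, "POSIXct")) tt else
    as.POSIXct(as.character(tt), tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  x <- suppressWarnings(as.numeric(df[[column_map[["x"]]]]))
  y <- suppressWarnings(as.numeric(df[[column_map[["y"]]]]))
  ok <- !is.na(t) & is.finite(x) & is.finite(y) & !is.na(id) & nzchar(id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing/unparseable fields dropped")
  keep <- which(ok)
  out <- lapply(split(keep, id[keep]), function(i) {
    track(id[i[1]], t[i], x[i], y[i])
  })
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Drop the initial acclimation period of a track
#'
#' Removes all fixes taken within `period_hours` of the first fix (half-open:
#' a fix at exactly `period_hours` after the start is kept). Trapping and
#' collaring bias the first hours of movement data, so analyses start after
#' this exclusion window (24 h by default).
#'
#' @param tr a [track()].
#' @param period_hours non-negative exclusion period in hours.
#' @return The track with the initial period removed.
#' @export
drop_initial_period <- function(tr, period_hours = 24) {
  stopifnot(period_hours >= 0)
  cutoff <- as.numeric(tr$t[1]) + period_hours * 3600
  keep <- as.numeric(tr$t) >= cutoff
  if (sum(keep) < 2) stop_degenerate(track_id(tr), sum(keep))
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("id", "crs_note")] <- attributes(tr)[c("id", "crs_note")]
  class(out) <- class(tr)
  out
}

#' Subsample a track to a nominal sampling interval
#'
#' Greedy forward pass: the first fix is kept; from each kept fix at time
#' `t`, the fix closest to `t + interval` among those within
#' `t + interval - tolerance` and `t + interval + tolerance` is kept next.
#' If no fix falls in that window, the earliest fix after
#' `t + interval + tolerance` is kept and the gap is recorded. No
#' interpolation is ever performed: output fixes are a subset of input fixes.
#'
#' @param tr a [track()].
#' @param interval_hours nominal sampling interval in hours (default 12).
#' @param tolerance_hours tolerance around the nominal interval in hours
#'   (default 1); must be less than half the interval.
#' @return An object of class `dew_regular_track` (also a `dew_track`) with
#'   attributes `interval_hours`, `tolerance_hours`, `regular_fraction` (the
#'   fraction of consecutive kept gaps within interval +/- tolerance), and
#'   `gap_hours` (lengths of the irregular gaps).
#' @export
subsample <- function(tr, interval_hours = 12, tolerance_hours = 1) {
  stopifnot(interval_hours > 0, tolerance_hours >= 0,
            tolerance_hours < interval_hours / 2)
  tn <- as.numeric(tr$t)
  iv <- interval_hours * 3600
  tol <- tolerance_hours * 3600
  n <- length(tn)
  keep <- integer(n)
  keep[1] <- 1L
  m <- 1L
  cur <- 1L
  repeat {
    target <- tn[cur] + iv
    cand <- which(tn >= target - tol & tn <= target + tol & tn > tn[cur])
    if (length(cand)) {
      nxt <- cand[which.min(abs(tn[cand] - target))]
    } else {
      later <- which(tn > target + tol)
      if (!length(later)) break
      nxt <- later[1]
    }
    m <- m + 1L
    keep[m] <- nxt
    cur <- nxt
  }
  keep <- keep[seq_len(m)]
  if (m < 2) stop_degenerate(track_id(tr), m)
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("id", "crs_note")] <- attributes(tr)[c("id", "crs_note")]
  g <- gaps_hours(out$t)
  regular <- abs(g - interval_hours) <= tolerance_hours
  attr(out, "interval_hours") <- interval_hours
  attr(out, "tolerance_hours") <- tolerance_hours
  attr(out, "regular_fraction") <- mean(regular)
  attr(out, "gap_hours") <- g[!regular]
  class(out) <- c("dew_regular_track", "dew_track", "data.frame")
  out
}

#' Fraction of consecutive gaps at the nominal sampling interval
#'
#' The continuity assumption behind rolling-window analysis of the
#' displacement series is considered met when more than 98% of consecutive
#' gaps lie within the nominal interval +/- tolerance; a warning is emitted
#' below that guard.
#'
#' @param rt a regular track from [subsample()].
#' @param warn_below emit a warning when the fraction falls below this value.
#' @return The regular fraction, a proportion in `[0, 1]`.
#' @export
regularity_fraction <- function(rt, warn_below = 0.98) {
  stopifnot(inherits(rt, "dew_regular_track"), nrow(rt) >= 2)
  g <- gaps_hours(rt$t)
  f <- mean(abs(g - attr(rt, "interval_hours")) <= attr(rt, "tolerance_hours"))
  if (f < warn_below)
    warning(sprintf("track '%s': only %.1f%% of gaps are regular (guard %.0f%%)",
                    track_id(rt), 100 * f, 100 * warn_below), call. = FALSE)
  f
}
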