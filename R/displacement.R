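#' Net squared displacement of a track
#'
#' The net squared displacement (NSD) of fix `t` is the squared Euclidean
#' distance in m^2 from a start location `(x_s, y_s)` to the fix:
#' `NSD = (x_t - x_s)^2 + (y_t - y_s)^2`. Its kilometer-scale companion is
#' `nNSD = sqrt(NSD) / 1000`, the plain Euclidean distance in km; despite
#' the name it is a distance, not a squared quantity. The start location
#' defaults to the first fix of the (cleaned) track, i.e. the trapping
#' location after the initial exclusion period.
#'
#' @param rt a track, normally a regular track from [subsample()].
#' @param origin optional numeric `c(x, y)` start location in meters;
#'   defaults to the first fix.
#' @return An object of class `dew_displacement`: a data frame with columns
#'   `t`, `nsd` (m^2) and `nnsd` (km), plus attributes `id`, `origin`,
#'   `interval_hours` (when available) and `reversed = FALSE`.
#' @examples
#' tr <- track("f1", as.POSIXct("2021-01-01", tz = "UTC") + 43200 * (0:2),
#'             x = c(0, 3000, 0), y = c(0, 4000, 0))
#' nsd(tr)$nnsd  # 0, 5, 0 km
#' @export
nsd <- function(rt, origin = NULL) {
  stopifnot(nrow(rt) >= 2)
  if (is.null(origin)) origin <- c(rt$x[1], rt$y[1])
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  d2 <- (rt$x - origin[1])^2 + (rt$y - origin[2])^2
  out <- data.frame(t = rt$t, nsd = d2, nnsd = sqrt(d2) / 1000)
  attr(out, "id") <- track_id(rt)
  attr(out, "origin") <- origin
  attr(out, "interval_hours") <- attr(rt, "interval_hours")
  attr(out, "reversed") <- FALSE
  class(out) <- c("dew_displacement", "data.frame")
  out
}

#' Reverse a displacement series
#'
#' Reverses the order of the nNSD values while keeping the timestamps in
#' original order, and flips the `reversed` flag. This is the input for the
#' reverse rolling-window pass that locates the end of a transient phase:
#' the same values are read backwards, displacement is not recomputed from
#' the final fix.
#'
#' @param ds a displacement series from [nsd()].
#' @return A `dew_displacement` with `nsd`/`nnsd` reversed and
#'   `reversed` negated. Applying [reverse_series()] twice restores the input.
#' @export
reverse_series <- function(ds) {
  stopifnot(inherits(ds, "dew_displacement"))
  ds$nsd <- rev(ds$nsd)
  ds$nnsd <- rev(ds$nnsd)
  attr(ds, "reversed") <- !attr(ds, "reversed")
  ds
}

#' Write a displacement series to TSV
#'
#' @param ds a displacement series from [nsd()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_displacement <- function(ds, path) {
  utils::write.table(
    data.frame(t = format(ds$t, "%Y-%m-%dT%H:%M:%S"),
               nsd = ds$nsd, nnsd = ds$nnsd),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
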