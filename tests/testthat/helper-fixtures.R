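# Shared fixtures and independent brute-force oracles.

T0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")

# Track with fixes at the given hours since T0.
hours_track <- function(hours, x = NULL, y = NULL, id = "t1") {
  n <- length(hours)
  if (is.null(x)) x <- seq_len(n) * 10
  if (is.null(y)) y <- rep(0, n)
  track(id, T0 + hours * 3600, x, y)
}

# Noiseless two-range step track: n1 fixes at c1, n2 fixes at c2.
step_track <- function(n1, n2, c1 = c(0, 0), c2 = c(8000, 0),
                       interval_hours = 12, id = "step") {
  n <- n1 + n2
  track(id, T0 + (seq_len(n) - 1) * interval_hours * 3600,
        c(rep(c1[1], n1), rep(c2[1], n2)),
        c(rep(c1[2], n1), rep(c2[2], n2)))
}

# Displacement series straight from nNSD values (12 h grid).
nnsd_series <- function(nnsd, interval_hours = 12) {
  out <- data.frame(t = T0 + (seq_along(nnsd) - 1) * interval_hours * 3600,
                    nsd = (nnsd * 1000)^2, nnsd = nnsd)
  attr(out, "id") <- "synthetic"
  attr(out, "interval_hours") <- interval_hours
  attr(out, "reversed") <- FALSE
  class(out) <- c("dew_displacement", "data.frame")
  out
}

# Indicator table with prescribed warning flags (for run-detection tests).
warning_indicators <- function(warnings, window_points = 10) {
  nw <- length(warnings)
  out <- data.frame(window_index = seq_len(nw), first = seq_len(nw),
                    last = seq_len(nw) + window_points - 1L,
                    sd_raw = 1, acf_raw = 0, f_sd = 0, f_acf = 0,
                    strength = ifelse(warnings, 10, 0), warning = warnings)
  class(out) <- c("dew_indicators", "data.frame")
  out
}

# Brute-force oracles, independent of the package's vectorized paths.
bf_sd <- function(v) {
  m <- 0
  for (z in v) m <- m + z
  m <- m / length(v)
  ss <- 0
  for (z in v) ss <- ss + (z - m)^2
  sqrt(ss / (length(v) - 1))
}

bf_acf1 <- function(v) {
  n <- length(v)
  m <- 0
  for (z in v) m <- m + z
  m <- m / n
  num <- 0
  for (i in 1:(n - 1)) num <- num + (v[i] - m) * (v[i + 1] - m)
  den <- 0
  for (z in v) den <- den + (z - m)^2
  num / den
}
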