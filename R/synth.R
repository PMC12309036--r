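#' Configuration for the synthetic track simulator
#'
#' The simulator emulates the three-phase structure of a dispersal event:
#' a stationary residency phase S1 (positions fluctuate around a fixed
#' centroid, modelled as a discretized Ornstein-Uhlenbeck process), an
#' optional transient phase T (constant-velocity drift from the first to
#' the second centroid with additive positional noise), and a second
#' stationary phase S2. Non-dispersing controls stay in S1 throughout.
#'
#' Default magnitudes follow the envelope of rural red fox telemetry:
#' 12 h fixes, stationary positional scale of 300 m per coordinate, a mean
#' reversion rate of 0.1 per hour (about a 10 h relaxation time, so
#' consecutive 12 h fixes are only weakly correlated), relocation over
#' about a week, and a centroid separation of 8 km.
#'
#' @param seed integer seed; the same config always yields the same track.
#' @param id individual label for the generated track.
#' @param interval_hours nominal sampling interval (default 12).
#' @param n_days_s1,n_days_t,n_days_s2 phase durations in days.
#' @param c1,c2 range centroids, numeric `c(x, y)` in meters.
#' @param ou_sigma stationary positional standard deviation per coordinate
#'   in meters (> 0).
#' @param ou_theta mean-reversion rate per hour (> 0).
#' @param transient_speed_noise positional noise during the transient
#'   phase, meters.
#' @param jitter_hours sampling-time jitter, uniform within plus/minus this
#'   many hours (must stay below half the interval).
#' @param disperser logical; `FALSE` yields a control residing at `c1`.
#' @return A list of class `dew_sim_config`.
#' @export
sim_config <- function(seed = 1L, id = "sim1", interval_hours = 12,
                       n_days_s1 = 45, n_days_t = 7, n_days_s2 = 45,
                       c1 = c(0, 0), c2 = c(8000, 0),
                       ou_sigma = 300, ou_theta = 0.1,
                       transient_speed_noise = 300,
                       jitter_hours = 0.25, disperser = TRUE) {
  stopifnot(interval_hours > 0, n_days_s1 >= 0, n_days_t >= 0,
            n_days_s2 >= 0, ou_sigma > 0, ou_theta > 0,
            transient_speed_noise >= 0,
            jitter_hours >= 0, jitter_hours < interval_hours / 2)
  structure(list(seed = as.integer(seed), id = id,
                 interval_hours = interval_hours,
                 n_days_s1 = n_days_s1, n_days_t = n_days_t,
                 n_days_s2 = n_days_s2, c1 = c1, c2 = c2,
                 ou_sigma = ou_sigma, ou_theta = ou_theta,
                 transient_speed_noise = transient_speed_noise,
                 jitter_hours = jitter_hours, disperser = disperser),
            class = "dew_sim_config")
}

#' Simulate a GPS track with known ground truth
#'
#' Positions follow an exactly discretized Ornstein-Uhlenbeck process
#' around `c1` during S1 (`x_{k+1} = c + (x_k - c) a + s sqrt(1 - a^2) e`,
#' `a = exp(-theta dt)`, stationary sd `s` per coordinate), a linear drift
#' from `c1` to `c2` with additive Gaussian noise during T, and OU around
#' `c2` during S2. The true transition starts midway between the last S1
#' fix and the first transient fix and lasts `n_days_t` days. Controls
#' (`disperser = FALSE`) remain in OU residency at `c1` for the combined
#' duration.
#'
#' @param cfg a [sim_config()].
#' @param t0 start time of the track.
#' @return A [track()] with attribute `truth`: a list with `disperser`,
#'   `c1`, `c2`, `t1_hours` (transition start, hours from the first fix),
#'   `dt_hours`, and `distance_km`.
#' @export
simulate_track <- function(cfg, t0 = as.POSIXct("2021-01-01", tz = "UTC")) {
  iv <- cfg$interval_hours
  n1 <- round(cfg$n_days_s1 * 24 / iv)
  nt <- if (cfg$disperser) round(cfg$n_days_t * 24 / iv) else 0L
  n2 <- if (cfg$disperser) round(cfg$n_days_s2 * 24 / iv) else 0L
  n <- n1 + nt + n2
  if (n < 2) stop("config yields a track with fewer than 2 fixes",
                  call. = FALSE)
  a <- exp(-cfg$ou_theta * iv)
  innov_sd <- cfg$ou_sigma * sqrt(1 - a^2)
  t1_true <- (n1 - 0.5) * iv        # midway between last S1 and first T fix
  dt_true <- nt * iv
  xy <- local_seed(cfg$seed, {
    pos <- matrix(NA_real_, n, 2)
    pos[1, ] <- cfg$c1 + stats::rnorm(2, 0, cfg$ou_sigma)
    for (k in 2:n) {
      tk <- (k - 1) * iv
      if (!cfg$disperser || tk < t1_true) {                 # S1 residency
        pos[k, ] <- cfg$c1 + (pos[k - 1, ] - cfg$c1) * a +
          stats::rnorm(2, 0, innov_sd)
      } else if (nt > 0 && tk < t1_true + dt_true) {        # transient drift
        w <- (tk - t1_true) / dt_true
        mu <- cfg$c1 + w * (cfg$c2 - cfg$c1)
        pos[k, ] <- mu + stats::rnorm(2, 0, cfg$transient_speed_noise)
      } else {                                              # S2 residency
        prev_in_s2 <- nt > 0 || (k - 2) * iv >= t1_true
        from <- if (prev_in_s2) pos[k - 1, ] else
          cfg$c2 + stats::rnorm(2, 0, cfg$ou_sigma)         # step arrival
        pos[k, ] <- cfg$c2 + (from - cfg$c2) * a +
          stats::rnorm(2, 0, innov_sd)
      }
    }
    jit <- if (cfg$jitter_hours > 0)
      stats::runif(n, -cfg$jitter_hours, cfg$jitter_hours) else numeric(n)
    jit[1] <- 0
    list(pos = pos, t = t0 + ((seq_len(n) - 1) * iv + jit) * 3600)
  })
  tr <- track(cfg$id, xy$t, xy$pos[, 1], xy$pos[, 2],
              crs_note = "synthetic projected meters")
  attr(tr, "truth") <- list(
    disperser = cfg$disperser, c1 = cfg$c1, c2 = cfg$c2,
    t1_hours = if (cfg$disperser) t1_true else NA_real_,
    dt_hours = if (cfg$disperser) dt_true else NA_real_,
    distance_km = if (cfg$disperser) sqrt(sum((cfg$c2 - cfg$c1)^2)) / 1000
                  else NA_real_)
  tr
}

#' Ground truth of a simulated track
#'
#' @param tr a track from [simulate_track()].
#' @return The `truth` attribute (a list), or `NULL` for real tracks.
#' @export
track_truth <- function(tr) attr(tr, "truth")

#' Generate a labelled cohort of synthetic tracks
#'
#' Draws dispersers with relocation distances, transient durations,
#' stationary scales and phase lengths sampled uniformly from
#' `parameter_ranges`, plus stationary controls, all reproducible from one
#' seed. Default ranges span the dispersal envelope observed in rural red
#' foxes: distances of 2.46 to 16.21 km and transient phases of 1 to 28
#' days.
#'
#' @param n_dispersers,n_controls cohort composition.
#' @param parameter_ranges named list of length-2 ranges:
#'   `distance_km`, `duration_days`, `ou_sigma` (m), `n_days_s` (length of
#'   each stationary phase, days).
#' @param seed integer seed for the cohort draw.
#' @param interval_hours nominal sampling interval.
#' @return A named list of tracks (ids `D1..` for dispersers, `C1..` for
#'   controls), each carrying its `truth` attribute.
#' @export
make_cohort <- function(n_dispersers = 8, n_controls = 14,
                        parameter_ranges = list(
                          distance_km = c(2.46, 16.21),
                          duration_days = c(1, 28),
                          ou_sigma = c(200, 400),
                          n_days_s = c(35, 60)),
                        seed = 1L, interval_hours = 12) {
  stopifnot(n_dispersers >= 0, n_controls >= 0)
  pr <- parameter_ranges
  draws <- local_seed(seed, {
    nd <- n_dispersers
    list(distance = stats::runif(nd, pr$distance_km[1], pr$distance_km[2]),
         angle = stats::runif(nd, 0, 2 * pi),
         duration = stats::runif(nd, pr$duration_days[1], pr$duration_days[2]),
         sig_d = stats::runif(nd, pr$ou_sigma[1], pr$ou_sigma[2]),
         s1_d = stats::runif(nd, pr$n_days_s[1], pr$n_days_s[2]),
         s2_d = stats::runif(nd, pr$n_days_s[1], pr$n_days_s[2]),
         sig_c = stats::runif(n_controls, pr$ou_sigma[1], pr$ou_sigma[2]),
         len_c = stats::runif(n_controls, 2 * pr$n_days_s[1], 2 * pr$n_days_s[2]))
  })
  tracks <- list()
  for (i in seq_len(n_dispersers)) {
    c2 <- 1000 * draws$distance[i] * c(cos(draws$angle[i]), sin(draws$angle[i]))
    cfg <- sim_config(seed = seed + i, id = paste0("D", i),
                      interval_hours = interval_hours,
                      n_days_s1 = draws$s1_d[i], n_days_t = draws$duration[i],
                      n_days_s2 = draws$s2_d[i],
                      c1 = c(0, 0), c2 = c2, ou_sigma = draws$sig_d[i],
                      disperser = TRUE)
    tracks[[cfg$id]] <- simulate_track(cfg)
  }
  for (i in seq_len(n_controls)) {
    cfg <- sim_config(seed = seed + 10000 + i, id = paste0("C", i),
                      interval_hours = interval_hours,
                      n_days_s1 = draws$len_c[i], n_days_t = 0, n_days_s2 = 0,
                      ou_sigma = draws$sig_c[i], disperser = FALSE)
    tracks[[cfg$id]] <- simulate_track(cfg)
  }
  tracks
}

#' Write a cohort of tracks to CSV with a ground-truth sidecar
#'
#' The CSV uses the same dialect [read_tracks()] consumes (columns `id`,
#' `timestamp`, `x`, `y`); the sidecar JSON holds each track's ground
#' truth so downstream tests never re-derive labels from the generator.
#'
#' @param tracks named list of tracks from [make_cohort()].
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = track_id(tr),
               timestamp = format(tr$t, "%Y-%m-%dT%H:%M:%S"),
               x = tr$x, y = tr$y)
  }))
  utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  truth <- lapply(tracks, track_truth)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
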