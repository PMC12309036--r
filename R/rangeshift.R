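#' Criteria for calling two ranges spatially distinct
#'
#' A range shift flagged by the EWS detector is confirmed only when the two
#' fitted home ranges are genuinely distinct in space: the centroids must be
#' at least `min_centroid_distance_km` apart (a species-specific distance;
#' 2 km for red foxes, whose rural home ranges are small -- a 2 km-radius
#' disc covers about 13 km^2), the 50% use areas must not overlap, each must
#' contain at least `min_fixes_per_range` fixes of its own phase, and the
#' range-shift test must reject the single-range null at level `alpha`.
#'
#' @param min_centroid_distance_km minimum centroid separation in km.
#' @param overlap_quantile probability mass of the use area tested for
#'   overlap (default 0.50, the core area).
#' @param min_fixes_per_range minimum own-phase fixes inside each core area.
#' @param alpha significance level for the range-shift F-test.
#' @return A list of class `dew_shift_criteria`.
#' @export
shift_criteria <- function(min_centroid_distance_km = 2,
                           overlap_quantile = 0.50,
                           min_fixes_per_range = 2,
                           alpha = 0.05) {
  stopifnot(overlap_quantile > 0, overlap_quantile < 1,
            min_centroid_distance_km >= 0, min_fixes_per_range >= 1)
  structure(list(min_centroid_distance_km = min_centroid_distance_km,
                 overlap_quantile = overlap_quantile,
                 min_fixes_per_range = min_fixes_per_range,
                 alpha = alpha),
            class = "dew_shift_criteria")
}

#' Initial two-range clustering of a track
#'
#' Runs 2-means on the (x, y) coordinates (deterministically seeded, 10
#' restarts, best inertia kept) and orders the clusters in time: the cluster
#' whose fixes lie earlier on average is the first range S1. The initial
#' transition time is the midpoint of the time gap at the assignment
#' changeover that best separates S1 labels from S2 labels.
#'
#' @param rt a track (normally a regular track).
#' @param seed integer seed for the k-means restarts.
#' @return A list with `c1`, `c2` (centroid coordinates in meters),
#'   `t1_init_hours` (hours from the first fix), `assignment` (1 = S1,
#'   2 = S2 per fix) and `ok` (`FALSE` when clustering collapsed).
#' @export
init_clusters <- function(rt, seed = 42L) {
  n <- nrow(rt)
  xy <- cbind(rt$x, rt$y)
  km <- tryCatch(
    local_seed(seed, stats::kmeans(xy, centers = 2, nstart = 10)),
    error = function(e) NULL)
  if (is.null(km) || any(km$size == 0))
    return(list(ok = FALSE, c1 = NULL, c2 = NULL,
                t1_init_hours = NA_real_, assignment = rep(NA_integer_, n)))
  tt <- hours_from_start(rt$t)
  ass <- km$cluster
  if (mean(tt[ass == 1]) > mean(tt[ass == 2])) {
    ass <- 3L - ass
    km$centers <- km$centers[2:1, , drop = FALSE]
  }
  # best changeover: split s maximizing (# S1 labels in 1..s) + (# S2 in s+1..n)
  is1 <- as.integer(ass == 1L)
  score <- cumsum(is1)[-n] + (sum(1L - is1) - cumsum(1L - is1)[-n])
  s <- which.max(score)
  list(ok = TRUE,
       c1 = unname(km$centers[1, ]), c2 = unname(km$centers[2, ]),
       t1_init_hours = (tt[s] + tt[s + 1]) / 2,
       assignment = ass)
}

hours_from_start <- function(t) (as.numeric(t) - as.numeric(t)[1]) / 3600

# Transition weight: 0 in S1, linear ramp over (t1, t1 + dt), 1 in S2.
shift_weight <- function(tt, t1, dt) {
  if (dt <= 0) return(as.numeric(tt > t1))
  pmin(pmax((tt - t1) / dt, 0), 1)
}

# Profiled residual sum of squares: given the transition window, the
# centroids that minimize the RSS solve a 2-column linear least-squares
# problem shared by x and y.
shift_profile <- function(tt, x, y, t1, dt) {
  w <- shift_weight(tt, t1, dt)
  W <- cbind(1 - w, w)
  XtX <- crossprod(W)
  if (abs(det(XtX)) < 1e-10 * max(XtX)^2)
    return(list(rss = Inf, c1 = c(NA, NA), c2 = c(NA, NA)))
  beta <- solve(XtX, crossprod(W, cbind(x, y)))
  resid <- cbind(x, y) - W %*% beta
  list(rss = sum(resid^2), c1 = unname(beta[1, ]), c2 = unname(beta[2, ]))
}

#' Fit a two-range shift model by nonlinear least squares
#'
#' The mean location is modelled as a first centroid `c1` up to the
#' transition start `t1`, a linear interpolation from `c1` to `c2` over the
#' transition duration `dt`, and `c2` afterwards. The parameters minimize
#' the sum of squared distances of the fixes to the mean path; for a fixed
#' transition window the optimal centroids are a linear least-squares
#' solution, so only `(t1, dt)` are searched numerically (all single
#' change-point splits as starting candidates, then Nelder-Mead polish).
#'
#' The residual scale per coordinate is `sigma = sqrt(RSS / (2n - 6))`, and
#' circular bivariate-Gaussian use-area radii are
#' `r_p = sigma * sqrt(-2 * log(1 - p))` for p = 0.50 and 0.95.
#'
#' @param rt a track.
#' @param init initial values from [init_clusters()]; computed when `NULL`.
#' @param seed seed forwarded to [init_clusters()].
#' @return A list of class `dew_rangeshift_fit`: centroids `c1`, `c2`,
#'   transition start `t1_hours` and duration `dt_hours` (hours from the
#'   first fix), `sigma_m`, `centroid_distance_km`, `r50_m`, `r95_m`,
#'   own-phase fix counts `n1`, `n2`, the fitted `rss`, phase labels, and
#'   `converged`.
#' @export
fit_shift <- function(rt, init = NULL, seed = 42L) {
  if (is.null(init)) init <- init_clusters(rt, seed = seed)
  n <- nrow(rt)
  tt <- hours_from_start(rt$t)
  if (!isTRUE(init$ok)) {
    out <- list(converged = FALSE, c1 = c(NA, NA), c2 = c(NA, NA),
                t1_hours = NA_real_, dt_hours = NA_real_, sigma_m = NA_real_,
                centroid_distance_km = NA_real_, r50_m = NA_real_,
                r95_m = NA_real_, n1 = 0L, n2 = 0L, rss = NA_real_,
                phase = rep(NA_character_, n), t0 = rt$t[1], n = n)
    class(out) <- "dew_rangeshift_fit"
    return(out)
  }
  x <- rt$x; y <- rt$y
  # coarse pass: every single change-point split, instantaneous transition
  best <- list(rss = Inf)
  for (s in seq_len(n - 1)) {
    t1c <- (tt[s] + tt[s + 1]) / 2
    p <- shift_profile(tt, x, y, t1c, 0)
    if (p$rss < best$rss) { best <- p; best$t1 <- t1c; best$dt <- 0 }
  }
  # include the clustering's own changeover among the starts
  pc <- shift_profile(tt, x, y, init$t1_init_hours, 0)
  if (pc$rss < best$rss) { best <- pc; best$t1 <- init$t1_init_hours; best$dt <- 0 }
  span <- tt[n] - tt[1]
  obj <- function(par) {
    t1 <- min(max(par[1], tt[1]), tt[n])
    dt <- min(max(par[2], 0), span)
    shift_profile(tt, x, y, t1, dt)$rss
  }
  opt <- tryCatch(
    stats::optim(c(best$t1, max(best$dt, span / n)), obj,
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  converged <- TRUE
  if (!is.null(opt) && opt$value <= best$rss + 1e-12) {
    t1 <- min(max(opt$par[1], tt[1]), tt[n])
    dt <- min(max(opt$par[2], 0), span)
  } else {
    # polish failed; fall back to the best change-point split
    t1 <- best$t1; dt <- best$dt
    converged <- !is.null(opt)
    if (is.null(opt))
      warning("transition-window optimization failed; using the best ",
              "change-point split", call. = FALSE)
  }
  p <- shift_profile(tt, x, y, t1, dt)
  df <- 2 * n - 6
  sigma <- if (df > 0) sqrt(p$rss / df) else NA_real_
  phase <- ifelse(tt <= t1, "S1", ifelse(tt >= t1 + dt, "S2", "T"))
  r50 <- sigma * sqrt(-2 * log(1 - 0.50))
  r95 <- sigma * sqrt(-2 * log(1 - 0.95))
  out <- list(converged = converged, c1 = p$c1, c2 = p$c2,
              t1_hours = t1, dt_hours = dt, sigma_m = sigma,
              centroid_distance_km = sqrt(sum((p$c1 - p$c2)^2)) / 1000,
              r50_m = r50, r95_m = r95,
              n1 = sum(phase == "S1"), n2 = sum(phase == "S2"),
              rss = p$rss, phase = phase, t0 = rt$t[1], n = n)
  class(out) <- "dew_rangeshift_fit"
  out
}

#' @export
print.dew_rangeshift_fit <- function(x, ...) {
  if (!x$converged && is.na(x$centroid_distance_km)) {
    cat("<range-shift fit> not converged (clustering collapsed)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<range-shift fit> centroid distance %.2f km, ",
                     "t1 = %.1f h, dt = %.1f h, sigma = %.0f m\n"),
              x$centroid_distance_km, x$t1_hours, x$dt_hours, x$sigma_m))
  invisible(x)
}

#' F-test for a range shift
#'
#' Compares the two-range shift model (6 mean parameters: two centroids,
#' transition start and duration) against the single-centroid null (2 mean
#' parameters) on the pooled x/y squared residuals, with `(4, 2n - 6)`
#' degrees of freedom. Small p-values indicate that the track is better
#' described by two ranges than one.
#'
#' @param fit a fit from [fit_shift()].
#' @param rt the track the fit was computed on.
#' @return The p-value; `1` when the sample is too small for the test.
#' @export
test_shift <- function(fit, rt) {
  n <- nrow(rt)
  df2 <- 2 * n - 6
  if (!fit$converged && is.na(fit$rss)) return(1)
  if (df2 <= 0) return(1)
  rss0 <- sum((rt$x - mean(rt$x))^2) + sum((rt$y - mean(rt$y))^2)
  rss1 <- fit$rss
  if (rss1 <= 0) return(0)
  f <- ((rss0 - rss1) / 4) / (rss1 / df2)
  stats::pf(max(f, 0), 4, df2, lower.tail = FALSE)
}

#' Evaluate the distinct-cluster criteria for a fitted shift
#'
#' Applies the [shift_criteria()] to a [fit_shift()] result: centroid
#' distance at least the species-specific minimum, disjoint core (50%) use
#' discs (centroid distance greater than the sum of the two disc radii), at
#' least the required number of own-phase fixes inside each core disc, and
#' a significant range-shift test. Fixes before `t1` belong to S1, fixes
#' after `t1 + dt` to S2; transient fixes belong to neither.
#'
#' @param fit a fit from [fit_shift()].
#' @param rt the track the fit was computed on.
#' @param crit a [shift_criteria()].
#' @return A list with `distinct_clusters` (the conjunction) and `details`
#'   carrying each sub-criterion (`distance_ok`, `overlap_ok`,
#'   `fixes_ok`, `test_ok`, `shift_pvalue`, counts, and radii).
#' @export
evaluate_criteria <- function(fit, rt, crit = shift_criteria()) {
  pval <- test_shift(fit, rt)
  if (!fit$converged || anyNA(fit$c1)) {
    return(list(distinct_clusters = FALSE,
                details = list(distance_ok = FALSE, overlap_ok = FALSE,
                               fixes_ok = FALSE, test_ok = FALSE,
                               shift_pvalue = pval,
                               centroid_distance_km = NA_real_,
                               r_core_m = NA_real_,
                               n_core_1 = 0L, n_core_2 = 0L)))
  }
  # core-area radius at the configured quantile (circular Gaussian)
  r_core <- fit$sigma_m * sqrt(-2 * log(1 - crit$overlap_quantile))
  dist_m <- fit$centroid_distance_km * 1000
  d1 <- sqrt((rt$x - fit$c1[1])^2 + (rt$y - fit$c1[2])^2)
  d2 <- sqrt((rt$x - fit$c2[1])^2 + (rt$y - fit$c2[2])^2)
  n_core_1 <- sum(fit$phase == "S1" & d1 <= r_core)
  n_core_2 <- sum(fit$phase == "S2" & d2 <= r_core)
  details <- list(
    distance_ok = fit$centroid_distance_km >= crit$min_centroid_distance_km,
    overlap_ok = dist_m > 2 * r_core,
    fixes_ok = n_core_1 >= crit$min_fixes_per_range &&
               n_core_2 >= crit$min_fixes_per_range,
    test_ok = pval < crit$alpha,
    shift_pvalue = pval,
    centroid_distance_km = fit$centroid_distance_km,
    r_core_m = r_core, n_core_1 = n_core_1, n_core_2 = n_core_2)
  list(distinct_clusters = details$distance_ok && details$overlap_ok &&
         details$fixes_ok && details$test_ok,
       details = details)
}

#' Full mechanistic range-shift analysis of a track
#'
#' Convenience wrapper chaining [init_clusters()], [fit_shift()],
#' [test_shift()] and [evaluate_criteria()].
#'
#' @inheritParams fit_shift
#' @inheritParams evaluate_criteria
#' @return The [fit_shift()] result with `shift_pvalue`,
#'   `distinct_clusters` and `criteria_details` added.
#' @export
range_shift_analysis <- function(rt, crit = shift_criteria(), seed = 42L) {
  fit <- fit_shift(rt, seed = seed)
  ev <- evaluate_criteria(fit, rt, crit)
  fit$shift_pvalue <- ev$details$shift_pvalue
  fit$distinct_clusters <- ev$distinct_clusters
  fit$criteria_details <- ev$details
  fit
}

#' Write a range-shift fit to JSON
#'
#' @param fit a fit from [fit_shift()] or [range_shift_analysis()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rangeshift <- function(fit, path) {
  keep <- setdiff(names(fit), c("phase", "t0"))
  jsonlite::write_json(fit[keep], path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
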