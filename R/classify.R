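#' Pipeline configuration
#'
#' Bundles the track-cleaning, EWS and range-shift settings of the full
#' dispersal-detection pipeline. See [ews_config()] and [shift_criteria()]
#' for the meaning of the individual settings.
#'
#' @param initial_exclusion_hours hours of data dropped after the first fix
#'   (trapping bias; default 24).
#' @param interval_hours nominal sampling interval in hours (default 12).
#' @param tolerance_hours subsampling tolerance in hours (default 1).
#' @param window_days rolling-window length in days (default 5).
#' @param threshold warning threshold on the composite signal strength
#'   (default 3.92).
#' @param k_consecutive consecutive warnings forming an EWS (default 4).
#' @param standardization_scope see [ews_config()].
#' @param min_centroid_distance_km,overlap_quantile,min_fixes_per_range,alpha
#'   see [shift_criteria()].
#' @param kmeans_seed seed for the deterministic 2-means initialization.
#' @return A list of class `dew_config` with components `track`, `ews`
#'   (an [ews_config()]) and `criteria` (a [shift_criteria()]).
#' @export
dispersews_config <- function(initial_exclusion_hours = 24,
                              interval_hours = 12, tolerance_hours = 1,
                              window_days = 5, threshold = 3.92,
                              k_consecutive = 4,
                              standardization_scope = "full_series",
                              min_centroid_distance_km = 2,
                              overlap_quantile = 0.50,
                              min_fixes_per_range = 2, alpha = 0.05,
                              kmeans_seed = 42L) {
  structure(list(
    track = list(initial_exclusion_hours = initial_exclusion_hours,
                 interval_hours = interval_hours,
                 tolerance_hours = tolerance_hours),
    ews = ews_config(window_days = window_days,
                     interval_hours = interval_hours,
                     threshold = threshold, k_consecutive = k_consecutive,
                     standardization_scope = standardization_scope),
    criteria = shift_criteria(min_centroid_distance_km,
                              overlap_quantile, min_fixes_per_range, alpha),
    kmeans_seed = as.integer(kmeans_seed)),
    class = "dew_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [dispersews_config()]; missing keys keep
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return A `dew_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(dispersews_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dispersews_config, vals)
}

#' Combine EWS detections and range-shift evaluation into a decision
#'
#' An individual is a disperser when (i) the rolling-window method detects
#' an EWS for both transitions (forward, S1 to T, and reverse, T to S2) at
#' the configured persistence, and (ii) the range-shift analysis identifies
#' two distinct clusters (centroid separation, disjoint core areas with
#' enough fixes, significant shift test).
#'
#' @param fwd,rev `dew_ews_detection` results for the forward and reverse
#'   pass (the reverse one carrying its mapped forward time).
#' @param shift_eval result of [evaluate_criteria()].
#' @param id individual label.
#' @return A list of class `dew_report` carrying the decision and all
#'   sub-criteria.
#' @export
classify_individual <- function(fwd, rev, shift_eval, id = "unknown") {
  both <- fwd$detected && rev$detected
  structure(list(
    id = id,
    ews_forward = fwd$detected, ews_reverse = rev$detected,
    both_ews = both,
    distinct_clusters = shift_eval$distinct_clusters,
    centroid_distance_km = shift_eval$details$centroid_distance_km,
    shift_pvalue = shift_eval$details$shift_pvalue,
    disperser = both && shift_eval$distinct_clusters,
    ews_timing = format_ews_timing(fwd),
    ews_time_hours = fwd$ews_time_hours,
    transient_duration_days =
      if (both) (rev$mapped_forward_time_hours - fwd$ews_time_hours) / 24
      else NA_real_),
    class = "dew_report")
}

#' Run the full dispersal-detection pipeline on one track
#'
#' Cleans the track (initial-period exclusion, subsampling to the nominal
#' interval), computes the nNSD series, runs bidirectional EWS detection at
#' the configured persistence and at k = 3, 4, 5 for the summary table,
#' always performs the range-shift analysis, and combines everything into
#' a per-individual report.
#'
#' @param tr a raw [track()].
#' @param config a [dispersews_config()].
#' @return A `dew_report` (see [classify_individual()]) extended with
#'   `ews_by_k` (named logical vector of bidirectional detection at
#'   k = 3, 4, 5), `regular_fraction`, `n_fixes`, and the underlying `fit`
#'   and `detections`.
#' @export
detect_dispersal <- function(tr, config = dispersews_config()) {
  tcfg <- config$track
  rt <- drop_initial_period(tr, tcfg$initial_exclusion_hours)
  rt <- subsample(rt, tcfg$interval_hours, tcfg$tolerance_hours)
  rf <- suppressWarnings(regularity_fraction(rt))
  ds <- nsd(rt)
  cfg <- config$ews
  bidir <- detect_bidirectional(ds, cfg)
  ews_by_k <- vapply(c(3L, 4L, 5L), function(k) {
    ck <- cfg; ck$k_consecutive <- k
    f <- detect_ews(bidir$forward$windows, ck, "forward")
    r <- detect_ews(bidir$reverse$windows, ck, "reverse")
    f$detected && r$detected
  }, logical(1))
  names(ews_by_k) <- paste0("k", 3:5)
  fit <- range_shift_analysis(rt, config$criteria, seed = config$kmeans_seed)
  ev <- list(distinct_clusters = fit$distinct_clusters,
             details = fit$criteria_details)
  rep <- classify_individual(bidir$forward, bidir$reverse, ev,
                             id = track_id(tr))
  rep$ews_by_k <- ews_by_k
  rep$regular_fraction <- rf
  rep$n_fixes <- nrow(rt)
  rep$fit <- fit
  rep$detections <- bidir
  rep
}

#' @export
print.dew_report <- function(x, ...) {
  cat(sprintf("<dispersal report> id=%s: %s\n", x$id,
              if (x$disperser) "DISPERSER" else "non-disperser"))
  cat(sprintf("  EWS forward %s / reverse %s; distinct clusters %s; distance %s km\n",
              x$ews_forward, x$ews_reverse, x$distinct_clusters,
              ifelse(is.na(x$centroid_distance_km), "NA",
                     sprintf("%.2f", x$centroid_distance_km))))
  if (!is.na(x$ews_timing))
    cat(sprintf("  EWS timing %s, %g h\n", x$ews_timing, x$ews_time_hours))
  invisible(x)
}

#' Run the pipeline over a cohort of tracks
#'
#' @param tracks a list of [track()] objects (e.g. from [read_tracks()] or
#'   [make_cohort()]).
#' @param config a [dispersews_config()].
#' @return A list of `dew_report`, named by individual id.
#' @export
run_pipeline <- function(tracks, config = dispersews_config()) {
  reports <- lapply(tracks, detect_dispersal, config = config)
  names(reports) <- vapply(reports, `[[`, character(1), "id")
  reports
}

#' Percentage of detections confirmed, to one decimal
#'
#' @param confirmed,detected counts.
#' @return `100 * confirmed / detected` rounded to 1 decimal; `NA` when
#'   nothing was detected.
#' @export
summary_percentage <- function(confirmed, detected) {
  if (detected == 0) return(NA_real_)
  round(100 * confirmed / detected, 1)
}

# "80%" when whole, "71.4%" otherwise
format_percentage <- function(p) {
  if (is.na(p)) return("NA")
  if (abs(p - round(p)) < 1e-9) sprintf("%d%%", as.integer(round(p)))
  else sprintf("%.1f%%", p)
}

#' Cohort summary of EWS detection vs spatial confirmation
#'
#' For each persistence k in 3, 4, 5: the number of individuals with a
#' bidirectional EWS, how many of those the range-shift analysis confirms
#' as two distinct clusters, and the confirmation percentage; plus the
#' individuals with distinct clusters but no EWS.
#'
#' @param reports list of reports from [run_pipeline()].
#' @return A data frame with one row per k: `k`, `n_ews`, `n_confirmed`,
#'   `pct_confirmed`, `n_no_ews`, `n_no_ews_distinct`, `pct_no_ews_distinct`,
#'   and formatted `label` columns.
#' @export
cohort_summary <- function(reports) {
  stopifnot(length(reports) >= 1)
  distinct <- vapply(reports, `[[`, logical(1), "distinct_clusters")
  rows <- lapply(3:5, function(k) {
    ews <- vapply(reports, function(r) r$ews_by_k[[paste0("k", k)]], logical(1))
    n_ews <- sum(ews)
    n_conf <- sum(ews & distinct)
    n_no <- sum(!ews)
    n_no_d <- sum(!ews & distinct)
    data.frame(k = k, n_ews = n_ews, n_confirmed = n_conf,
               pct_confirmed = summary_percentage(n_conf, n_ews),
               n_no_ews = n_no, n_no_ews_distinct = n_no_d,
               pct_no_ews_distinct = summary_percentage(n_no_d, n_no))
  })
  out <- do.call(rbind, rows)
  out$label <- vapply(out$pct_confirmed, format_percentage, character(1))
  out
}

#' Table of per-individual results
#'
#' One row per individual, mirroring the per-k EWS flags, cluster flags,
#' centroid distance and EWS timing of the study-style report table.
#'
#' @param reports list of reports from [run_pipeline()].
#' @return A data frame with one row per individual.
#' @export
cohort_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(id = r$id,
               ews_k3 = r$ews_by_k[["k3"]], ews_k4 = r$ews_by_k[["k4"]],
               ews_k5 = r$ews_by_k[["k5"]],
               distinct_clusters = r$distinct_clusters,
               centroid_distance_km = r$centroid_distance_km,
               shift_pvalue = r$shift_pvalue,
               ews_timing = ifelse(is.na(r$ews_timing), "", r$ews_timing),
               ews_time_hours = r$ews_time_hours,
               transient_duration_days = r$transient_duration_days,
               disperser = r$disperser,
               row.names = NULL)
  }))
}

#' Thresholds perturbed by a relative change
#'
#' @param u reference threshold (default 3.92).
#' @param rel_change relative perturbation (default 0.1, i.e. 10%).
#' @return Named numeric `c(decrease = , increase = )`, e.g. 3.528 and
#'   4.312 for the defaults.
#' @export
perturbed_thresholds <- function(u = 3.92, rel_change = 0.1) {
  c(decrease = u * (1 - rel_change), increase = u * (1 + rel_change))
}

#' Sensitivity of the detection count to the warning threshold
#'
#' Computes `S = (|lambda - lambda_i| / lambda) / (|u - u_i| / u)` for a
#' decrease and an increase of the threshold `u` by `rel_change`, where
#' `lambda` is the detection count at `u` and `lambda_i` the count at the
#' perturbed threshold. `S > 1` means the count responds more than
#' proportionally to the threshold (flagged `sensitive`).
#'
#' @param count_fn function mapping a threshold to a detection count.
#' @param u reference threshold.
#' @param rel_change relative perturbation of the threshold (default 0.1).
#' @return A data frame with rows `decrease` and `increase` and columns
#'   `u`, `u_i`, `lambda`, `lambda_i`, `S`, `sensitive`.
#' @examples
#' counts <- function(th) c(`3.528` = 11, `3.92` = 10, `4.312` = 7)[
#'   sprintf("%.3g", th)]
#' sensitivity(counts, u = 3.92)  # S = 1 (decrease), S = 3 (increase)
#' @export
sensitivity <- function(count_fn, u = 3.92, rel_change = 0.1) {
  stopifnot(rel_change > 0)
  lambda <- as.numeric(count_fn(u))
  if (is.na(lambda) || lambda <= 0)
    stop("sensitivity undefined: no detections at the reference threshold",
         call. = FALSE)
  side <- c(decrease = -1, increase = 1)
  rows <- lapply(names(side), function(nm) {
    u_i <- u * (1 + side[[nm]] * rel_change)
    lambda_i <- as.numeric(count_fn(u_i))
    S <- (abs(lambda - lambda_i) / lambda) / rel_change
    data.frame(u = u, u_i = u_i, lambda = lambda, lambda_i = lambda_i,
               S = S, sensitive = S > 1, row.names = nm)
  })
  do.call(rbind, rows)
}

#' Write cohort results to disk
#'
#' Writes the per-individual table as TSV, the cohort summary as TSV, and
#' the full reports as JSON.
#'
#' @param reports list of reports from [run_pipeline()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(cohort_table(reports), file.path(dir, "individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort_summary(reports), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  slim <- lapply(reports, function(r)
    r[setdiff(names(r), c("fit", "detections"))])
  jsonlite::write_json(slim, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
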