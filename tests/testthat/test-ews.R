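test_that("window_sd is the sample standard deviation with n-1 denominator", {
  v <- c(rep(0, 9), 2)
  expect_equal(window_sd(v), sqrt((9 * 0.04 + 3.24) / 9))  # 0.6325, mean 0.2
  expect_true(is.na(window_sd(rep(1.5, 10))))               # constant window
  set.seed(2)
  z <- rnorm(10)
  expect_equal(window_sd(3 * z), 3 * window_sd(z))          # homogeneity
  expect_equal(window_sd(v, variance_mode = TRUE), window_sd(v)^2)
})

test_that("window_acf1 matches the standard lag-1 estimator", {
  expect_equal(window_acf1(1:10), 0.7)                      # linear ramp, exact
  expect_true(window_acf1(rep(c(0, 1), 5)) < 0)             # alternating
  expect_equal(window_acf1(rep(c(0, 1), 5)), bf_acf1(rep(c(0, 1), 5)))
  expect_true(is.na(window_acf1(rep(2, 10))))
  # oracle equivalence against stats::acf on white noise
  set.seed(31)
  for (i in 1:25) {
    z <- rnorm(10)
    ref <- as.numeric(stats::acf(z, lag.max = 1, plot = FALSE,
                                 demean = TRUE)$acf[2])
    expect_equal(window_acf1(z), ref, tolerance = 1e-12)
  }
})

test_that("indicator_series slides one point at a time and standardizes", {
  set.seed(8)
  ds <- nnsd_series(cumsum(rnorm(20, 0, 0.2)))
  cfg <- ews_config()
  ind <- indicator_series(ds, cfg)
  expect_equal(nrow(ind), 11)                               # n - w + 1
  expect_equal(ind$window_index, 1:11)
  expect_equal(ind$last - ind$first + 1L, rep(10L, 11))
  expect_equal(mean(ind$f_sd), 0, tolerance = 1e-10)
  expect_equal(sd(ind$f_sd), 1, tolerance = 1e-10)
  expect_equal(mean(ind$f_acf), 0, tolerance = 1e-10)
  expect_equal(sd(ind$f_acf), 1, tolerance = 1e-10)
  expect_equal(ind$strength, abs(ind$f_sd) + abs(ind$f_acf))
})

test_that("constant series yields undefined indicators and no warnings", {
  ds <- nnsd_series(rep(3, 20))
  ind <- indicator_series(ds, ews_config())
  expect_true(all(is.na(ind$sd_raw)))
  expect_false(any(ind$warning))
})

test_that("too-short series raises a detection-infeasible error", {
  expect_error(indicator_series(nnsd_series(rnorm(12)), ews_config()),
               "too short")
})

test_that("strength is invariant to affine transforms of the raw indicators", {
  set.seed(9)
  ds <- nnsd_series(abs(cumsum(rnorm(40, 0, 0.3))))
  ind1 <- indicator_series(ds, ews_config())
  ds2 <- ds
  ds2$nnsd <- ds$nnsd * 4          # scales sd_raw by 4, acf unchanged
  ind2 <- indicator_series(ds2, ews_config())
  expect_equal(ind2$strength, ind1$strength, tolerance = 1e-10)
})

test_that("detect_ews reports the k-th window of the first run and its span", {
  warn <- rep(FALSE, 60); warn[48:51] <- TRUE
  det <- detect_ews(warning_indicators(warn), ews_config(k_consecutive = 4))
  expect_true(det$detected)
  expect_equal(det$ews_window_index, 51L)
  expect_equal(det$first_run_span, c(48L, 57L))
  expect_equal(format_ews_timing(det), "51 [48-57]")
  expect_equal(det$ews_time_hours, 612)                     # 51 x 12 h

  warn2 <- rep(FALSE, 20); warn2[1:4] <- TRUE
  det2 <- detect_ews(warning_indicators(warn2), ews_config(k_consecutive = 4))
  expect_equal(det2$ews_window_index, 4L)
  expect_equal(det2$first_run_span, c(1L, 10L))
  expect_equal(det2$ews_time_hours, 48)

  warn3 <- rep(FALSE, 12); warn3[c(5, 9)] <- TRUE           # isolated warnings
  det3 <- detect_ews(warning_indicators(warn3), ews_config(k_consecutive = 4))
  expect_false(det3$detected)
})

test_that("k = 1 accepts any warning; k beyond the window count never detects", {
  warn <- rep(FALSE, 15); warn[7] <- TRUE
  expect_true(detect_ews(warning_indicators(warn),
                         ews_config(k_consecutive = 1))$detected)
  expect_false(detect_ews(warning_indicators(rep(TRUE, 15)),
                          ews_config(k_consecutive = 16))$detected)
})

test_that("warning count is non-increasing in the threshold", {
  set.seed(12)
  ds <- nnsd_series(abs(cumsum(rnorm(60, 0, 0.3))))
  counts <- sapply(seq(0.5, 6, by = 0.5), function(th)
    sum(indicator_series(ds, ews_config(threshold = th))$warning))
  expect_true(all(diff(counts) <= 0))
})

test_that("bidirectional detection maps reverse indices back to forward time", {
  tr <- simulate_track(sim_config(seed = 21, n_days_s1 = 30, n_days_t = 4,
                                  n_days_s2 = 30, c2 = c(8000, 0)))
  ds <- nsd(subsample(tr))
  bid <- detect_bidirectional(ds, ews_config())
  expect_true(bid$both_detected)
  expect_lte(bid$forward$ews_time_hours, bid$reverse$mapped_forward_time_hours)
  expect_equal(bid$reverse$mapped_forward_index,
               nrow(ds) - bid$reverse$ews_window_index + 1L)
  # deterministic: identical inputs give identical detections
  bid2 <- detect_bidirectional(ds, ews_config())
  expect_identical(bid2$forward$ews_window_index, bid$forward$ews_window_index)
})

test_that("per-window indicators are reversal-invariant, so reverse warnings mirror forward ones", {
  set.seed(13)
  ds <- nnsd_series(abs(cumsum(rnorm(50, 0, 0.3))))
  f <- indicator_series(ds, ews_config())
  r <- indicator_series(reverse_series(ds), ews_config())
  expect_equal(r$sd_raw, rev(f$sd_raw), tolerance = 1e-12)
  expect_equal(r$acf_raw, rev(f$acf_raw), tolerance = 1e-12)
  expect_equal(r$warning, rev(f$warning))
})

test_that("expanding standardization is causal: early windows ignore the future", {
  set.seed(14)
  z <- abs(cumsum(rnorm(40, 0, 0.3)))
  cfg <- ews_config(standardization_scope = "expanding")
  full <- indicator_series(nnsd_series(z), cfg)
  short <- indicator_series(nnsd_series(z[1:30]), cfg)
  nw <- nrow(short)
  expect_equal(short$f_sd, full$f_sd[1:nw], tolerance = 1e-12)
  expect_equal(short$strength, full$strength[1:nw], tolerance = 1e-12)
})
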