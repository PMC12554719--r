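# RR preprocessing, HRV metrics and the composite autonomic indices.

test_that("artifact correction replaces ectopics and is idempotent", {
  clean <- rr_series(rep(c(790, 800, 810, 805), 30))
  out <- correct_artifacts(clean)
  expect_identical(out$rr, clean$rr)
  expect_equal(attr(out, "correction_report")$n_corrected, 0L)

  # one 2000 ms ectopic in an ~800 ms series
  x <- rep(c(795, 805, 800, 810), 25)
  x[50] <- 2000
  rr <- rr_series(x)
  corr <- correct_artifacts(rr)
  rep_ <- attr(corr, "correction_report")
  expect_equal(rep_$indices, 50L)
  local_med <- median(x[c(45:49, 51:55)])
  expect_lt(abs(corr$rr[50] - local_med) / local_med, 0.05)

  # idempotent: correcting a corrected series changes nothing
  twice <- correct_artifacts(corr)
  expect_equal(twice$rr, corr$rr)
  expect_equal(attr(twice, "correction_report")$n_corrected, 0L)

  # all-equal series unchanged
  const <- rr_series(rep(800, 40))
  expect_identical(correct_artifacts(const)$rr, const$rr)

  # more than 20% flagged is a quality failure
  y <- rep(800, 30)
  y[seq(1, 30, by = 3)] <- 2000
  expect_error(correct_artifacts(rr_series(y)),
               class = "ansflow_quality_error")
})

test_that("smoothness-priors detrending annihilates constants and lines", {
  const <- rr_series(rep(850, 200))
  out <- detrend_smoothness_priors(const)
  expect_lt(max(abs(out$detrended)), 1e-9)
  expect_equal(out$trend, rep(850, 200), tolerance = 1e-9)

  ramp <- rr_series(seq(700, 1000, length.out = 500))
  out2 <- detrend_smoothness_priors(ramp, lambda = 500)
  expect_lt(max(abs(out2$detrended)), 1e-6 * 300)

  # lambda = 0: trend equals the data, detrended is zero
  set.seed(4)
  z <- rr_series(800 + rnorm(50, 0, 30))
  out3 <- detrend_smoothness_priors(z, lambda = 0)
  expect_equal(out3$trend, z$rr, tolerance = 1e-12)

  expect_error(detrend_smoothness_priors(rr_series(c(800, 810))),
               class = "ansflow_size_error")
})

test_that("detrending is a linear operator", {
  set.seed(8)
  x <- 800 + rnorm(300, 0, 40)
  y <- 900 + 50 * sin(seq_len(300) / 20)
  lhs <- detrend_smoothness_priors(rr_series(2 * x + 3 * y))$detrended
  rhs <- 2 * detrend_smoothness_priors(rr_series(x))$detrended +
    3 * detrend_smoothness_priors(rr_series(y))$detrended
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(lhs)))
})

test_that("time-domain metrics match hand arithmetic", {
  m <- time_domain_metrics(rr_series(rep(800, 3)))
  expect_equal(m$mean_rr, 800)
  expect_equal(m$mean_hr, 75)
  expect_equal(m$rmssd, 0)

  expect_equal(time_domain_metrics(rr_series(c(800, 810, 790)))$rmssd,
               sqrt((10^2 + 20^2) / 2))
  expect_equal(time_domain_metrics(rr_series(rep(1000, 5)))$mean_hr, 60)
  expect_error(time_domain_metrics(rr_series(800)),
               class = "ansflow_size_error")
})

test_that("SD1 equals RMSSD/sqrt(2) as an exact identity", {
  for (s in 1:100) {
    set.seed(s)
    x <- 800 + cumsum(rnorm(60, 0, 10)) + rnorm(60, 0, 20)
    p <- poincare_metrics(x)
    r <- time_domain_metrics(x)$rmssd
    expect_equal(p$sd1, r / sqrt(2), tolerance = 1e-9)
  }
})

test_that("Poincare dispersions agree with the direct ellipse-axis geometry", {
  set.seed(12)
  x <- 850 + 30 * sin(seq_len(5000) / 15) + rnorm(5000, 0, 15)
  p <- poincare_metrics(x)
  # project the (RR_i, RR_{i+1}) scatter on the identity line and its normal
  x1 <- x[-length(x)]; x2 <- x[-1]
  minor <- sqrt(mean(((x2 - x1) / sqrt(2))^2))          # normal direction
  u <- (x1 + x2) / sqrt(2)                              # identity direction
  major <- sqrt(mean((u - mean(u))^2))
  expect_equal(p$sd1, minor, tolerance = 1e-9)
  expect_equal(p$sd2, major, tolerance = 0.02)  # edge effects O(1/n)

  # alternating series: all short-term, no long-term variability
  alt <- rep(c(800, 820), 50)
  expect_error(poincare_metrics(alt), class = "ansflow_degenerate_error")
  expect_error(poincare_metrics(rep(800, 50)),
               class = "ansflow_degenerate_error")
})

test_that("Baevsky stress index reproduces the constructed histogram case", {
  # 60/100 intervals in the bin centred at 800 ms, range 650-950 ms
  rr <- c(rep(800, 60), rep(c(650, 700, 750, 850, 900, 950),
                            length.out = 40))
  si <- baevsky_stress_index(rr, bin_width_ms = 50)
  expect_equal(si$mo_s, 0.8)
  expect_equal(si$amo_pct, 60)
  expect_equal(si$mxdmn_s, 0.3)
  expect_equal(si$si, 60 / (2 * 0.8 * 0.3))  # = 125
  expect_equal(si$sqrt_si, sqrt(125))

  # widening the range with a fixed mode strictly lowers SI
  rr_wide <- c(rep(800, 60), rep(c(600, 700, 750, 850, 900, 1000),
                                 length.out = 40))
  expect_lt(baevsky_stress_index(rr_wide)$si, si$si)

  # spreading mass out of the modal bin lowers SI at fixed range
  rr_spread <- c(rep(800, 20), rep(c(650, 700, 750, 850, 900, 950),
                                   length.out = 80))
  expect_lt(baevsky_stress_index(rr_spread)$si, si$si)

  expect_error(baevsky_stress_index(rep(800, 10)),
               class = "ansflow_size_error")
  expect_error(baevsky_stress_index(rep(800, 30)),
               class = "ansflow_degenerate_error")
})

test_that("composite indices are weighted z-score sums", {
  norms <- hrv_norms()
  at_norm <- list(mean_rr = norms$mean_rr[["mean"]],
                  rmssd = norms$rmssd[["mean"]],
                  mean_hr = norms$mean_hr[["mean"]],
                  sqrt_si = norms$sqrt_si[["mean"]],
                  # sd1/sd2 chosen so normalized units hit the norm means
                  sd1 = 35, sd2 = 65)
  expect_equal(compute_pnsi(at_norm, norms), 0, tolerance = 1e-12)
  expect_equal(compute_snsi(at_norm, norms), 0, tolerance = 1e-12)

  up_rr <- at_norm
  up_rr$mean_rr <- norms$mean_rr[["mean"]] + norms$mean_rr[["sd"]]
  expect_equal(compute_pnsi(up_rr, norms), 1 / 3, tolerance = 1e-12)

  up_hr <- at_norm
  up_hr$mean_hr <- norms$mean_hr[["mean"]] + norms$mean_hr[["sd"]]
  expect_equal(compute_snsi(up_hr, norms), 1 / 3, tolerance = 1e-12)

  missing <- at_norm
  missing$rmssd <- NULL
  expect_error(compute_pnsi(missing, norms), class = "ansflow_input_error")
})

test_that("norms can be overridden from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("mean_rr: [950, 100]", "weights_pnsi: [2, 1, 1]"), path)
  n <- read_norms(path)
  expect_equal(unname(n$mean_rr), c(950, 100))
  expect_equal(n$weights_pnsi, c(0.5, 0.25, 0.25))
  expect_equal(unname(n$rmssd), c(42, 15))  # default retained
  expect_error(read_norms(tempfile()), class = "ansflow_input_error")
})

test_that("the HRV pipeline is deterministic and robust to a single ectopic", {
  cfg <- synth_config(seed = 40, duration_s = 300)
  rr <- generate_rr_series(cfg)
  m1 <- hrv_pipeline(rr)
  m2 <- hrv_pipeline(rr)
  expect_identical(m1[c("mean_rr", "rmssd", "pnsi", "snsi")],
                   m2[c("mean_rr", "rmssd", "pnsi", "snsi")])

  # inject one ectopic: corrected metrics within 1% of the clean ones
  rr_bad <- rr
  rr_bad$rr[100] <- rr_bad$rr[100] + 700
  mb <- hrv_pipeline(rr_bad)
  expect_lt(abs(mb$mean_rr - m1$mean_rr) / m1$mean_rr, 0.01)
  expect_lt(abs(mb$rmssd - m1$rmssd) / m1$rmssd, 0.01)

  # a constant series degrades gracefully: HR defined, indices NA
  mc <- suppressWarnings(hrv_pipeline(rr_series(rep(800, 100))))
  expect_equal(mc$mean_hr, 75)
  expect_equal(mc$rmssd, 0)
  expect_true(is.na(mc$baevsky_si))
})

test_that("index monotonicity follows the autonomic interpretation", {
  pnsi_at <- function(a) {
    cfg <- synth_config(seed = 3, duration_s = 240, rsa_amplitude_ms = a)
    hrv_pipeline(generate_rr_series(cfg))$pnsi
  }
  vals <- vapply(c(5, 20, 35, 50, 65), pnsi_at, numeric(1))
  expect_true(all(diff(vals) > 0))  # deeper RSA -> more parasympathetic

  snsi_at <- function(mrr) {
    cfg <- synth_config(seed = 3, duration_s = 240, mean_rr_ms = mrr)
    hrv_pipeline(generate_rr_series(cfg))$snsi
  }
  vals2 <- vapply(c(1100, 1000, 900, 800, 700), snsi_at, numeric(1))
  expect_true(all(diff(vals2) > 0))  # higher HR -> more sympathetic
})

test_that("metrics ignore subject and phase labels", {
  cfg <- synth_config(seed = 6, duration_s = 120)
  a <- hrv_pipeline(generate_rr_series(cfg, subject_id = "a", phase = "pre"))
  b <- hrv_pipeline(generate_rr_series(cfg, subject_id = "b", phase = "post"))
  expect_identical(a[c("mean_rr", "rmssd", "sd1", "sd2", "pnsi", "snsi")],
                   b[c("mean_rr", "rmssd", "sd1", "sd2", "pnsi", "snsi")])
})
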