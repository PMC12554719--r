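# RR-interval preprocessing (threshold artifact correction, smoothness-priors
# detrending) and the HRV metric / composite index layer: mean RR/HR, RMSSD,
# Poincare SD1/SD2, Baevsky stress index, and the normalized-component
# PNSi/SNSi composites.

artifact_thresholds_ms <- c(very_low = 450, low = 350, medium = 250,
                          strong = 150, very_strong = 50)

#' Threshold-based RR artifact correction
#'
#' Flags every interval deviating from the local median (centred
#' `window`-beat window) by more than the level's threshold and replaces it
#' by cubic-spline interpolation over the unflagged beats.  The levels and
#' thresholds mirror the familiar very-low .. very-strong correction scale
#' (medium = 0.25 s).
#'
#' @param rr An [rr_series()].
#' @param level One of `"none"`, `"very_low"`, `"low"`, `"medium"`
#'   (default), `"strong"`, `"very_strong"`.
#' @param window Local-median window in beats (odd, default 11).
#' @return The corrected [rr_series()]; attribute `"correction_report"`
#'   holds the corrected indices and fraction.
#' @examples
#' rr <- rr_series(c(rep(800, 20), 2000, rep(800, 20)))
#' corrected <- correct_artifacts(rr)
#' attr(corrected, "correction_report")$n_corrected
#' @export
correct_artifacts <- function(rr, level = c("medium", "none", "very_low",
                                            "low", "strong", "very_strong"),
                              window = 11L) {
  stopifnot(inherits(rr, "rr_series"))
  level <- match.arg(level)
  x <- rr$rr
  report <- list(level = level, indices = integer(), n_corrected = 0L,
                 fraction = 0)
  if (level == "none" || length(x) < 3L) {
    attr(rr, "correction_report") <- report
    return(rr)
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  k <- min(window, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  loc_med <- runmed(x, k = k, endrule = "median")
  thr <- artifact_thresholds_ms[[level]]
  bad <- abs(x - loc_med) > thr
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > 0.20)
      stop_quality(sprintf(
        "%.0f%% of beats flagged as artifacts (> 20%%); series unusable",
        100 * frac))
    idx <- seq_along(x)
    x[bad] <- spline(idx[!bad], x[!bad], xout = idx[bad],
                     method = "natural")$y
    report$indices <- which(bad)
    report$n_corrected <- sum(bad)
    report$fraction <- frac
  }
  out <- rr_series(x, t = rr$t, subject_id = rr$subject_id, phase = rr$phase)
  attr(out, "correction_report") <- report
  out
}

#' Smoothness-priors detrending of an RR series
#'
#' Removes the slow trend `(I + lambda^2 D2' D2)^{-1} z` from the RR vector
#' `z`, where `D2` is the second-difference operator.  This is the standard
#' regularized detrender used before short-term HRV analysis; `lambda = 500`
#' gives a cut-off well below the respiratory band.  The system is solved
#' with a sparse symmetric positive-definite factorization (no dense
#' inverse).
#'
#' @param rr An [rr_series()] with at least 3 beats.
#' @param lambda Regularization parameter (>= 0, default 500).
#' @return List with `detrended` (zero-trend RR values, ms), `trend` (ms)
#'   and `lambda`.
#' @export
detrend_smoothness_priors <- function(rr, lambda = 500) {
  stopifnot(inherits(rr, "rr_series"))
  check_number(lambda, "lambda", lower = 0)
  z <- rr$rr
  n <- length(z)
  if (n < 3L) stop_size("smoothness-priors detrending needs >= 3 beats")
  i <- rep(seq_len(n - 2L), 3L)
  j <- c(seq_len(n - 2L), seq_len(n - 2L) + 1L, seq_len(n - 2L) + 2L)
  d2 <- Matrix::sparseMatrix(i = i, j = j,
                             x = rep(c(1, -2, 1), each = n - 2L),
                             dims = c(n - 2L, n))
  a <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2)
  # the smoother leaves constants invariant, so solve on the mean-centred
  # vector: avoids catastrophic cancellation at the lambda^2 scale and adds
  # one step of iterative refinement for the ill-conditioned system
  zc <- z - mean(z)
  trend_c <- as.numeric(Matrix::solve(a, zc))
  resid <- zc - as.numeric(a %*% trend_c)
  trend_c <- trend_c + as.numeric(Matrix::solve(a, resid))
  trend <- trend_c + mean(z)
  list(detrended = z - trend, trend = trend, lambda = lambda)
}

#' Time-domain HRV metrics
#'
#' @param rr An [rr_series()] (or plain numeric vector of ms intervals)
#'   with at least 2 beats.
#' @return List with `mean_rr` (ms), `mean_hr` (bpm, `60000 / mean_rr`)
#'   and `rmssd` (ms, root mean square of successive differences).
#' @examples
#' time_domain_metrics(rr_series(c(800, 810, 790)))$rmssd  # sqrt(250)
#' @export
time_domain_metrics <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2L) stop_size("RMSSD needs at least 2 intervals")
  d <- diff(x)
  list(mean_rr = mean(x), mean_hr = 60000 / mean(x),
       rmssd = sqrt(mean(d^2)))
}

#' Poincare plot dispersions SD1 and SD2
#'
#' SD1 (short-term variability, minor axis of the lag-1 Poincare ellipse)
#' and SD2 (long-term variability, major axis).  The successive-difference
#' dispersion uses the uncentred population second moment, which makes
#' `SD1 = RMSSD / sqrt(2)` an exact identity; `SD2^2 = max(0, 2 var(RR) -
#' SD1^2)` with the population variance of RR.
#'
#' @param rr An [rr_series()] or numeric vector (ms), at least 3 beats.
#' @return List with `sd1`, `sd2` (ms) and `sd1_sd2_ratio`.  A zero SD2
#'   (e.g. constant series) makes the ratio undefined and raises a
#'   degenerate-input error.
#' @export
poincare_metrics <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 3L) stop_size("Poincare metrics need at least 3 intervals")
  d <- diff(x)
  sd1 <- sqrt(mean(d^2) / 2)
  var_pop <- mean((x - mean(x))^2)
  sd2 <- sqrt(max(0, 2 * var_pop - mean(d^2) / 2))
  if (sd2 == 0)
    stop_degenerate("SD2 = 0: SD1/SD2 ratio undefined (constant series?)")
  list(sd1 = sd1, sd2 = sd2, sd1_sd2_ratio = sd1 / sd2)
}

#' Baevsky stress index
#'
#' `SI = AMo / (2 Mo MxDMn)` from the RR histogram: `Mo` is the midpoint of
#' the modal bin in seconds, `AMo` the percentage of intervals in that bin,
#' `MxDMn` the RR range in seconds.  Bins have fixed width (default 50 ms)
#' with centres anchored at integer multiples of the width; a modal-bin tie
#' goes to the lowest bin.  `sqrt(SI)` is also returned: the index has a
#' heavy right tail and the composite sympathetic index uses its square
#' root.
#'
#' @param rr An [rr_series()] or numeric vector (ms), at least 20 beats
#'   spanning more than one histogram bin.
#' @param bin_width_ms Histogram bin width in ms (default 50).
#' @return List with `si`, `sqrt_si`, `mo_s`, `amo_pct`, `mxdmn_s`.
#' @export
baevsky_stress_index <- function(rr, bin_width_ms = 50) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  check_number(bin_width_ms, "bin_width_ms", lower = 0, strict_lower = TRUE)
  if (length(x) < 20L)
    stop_size("the stress index needs at least 20 intervals")
  if (max(x) <= min(x))
    stop_degenerate("all RR intervals equal: MxDMn = 0, SI undefined")
  centre <- round(x / bin_width_ms)  # bin centres at k * bin_width
  counts <- table(centre)
  if (length(counts) < 2L)
    stop_degenerate("all RR intervals fall into one histogram bin")
  imax <- which(counts == max(counts))[1L]  # tie -> lowest bin
  mo_s <- as.numeric(names(counts)[imax]) * bin_width_ms / 1000
  amo_pct <- 100 * max(counts) / length(x)
  mxdmn_s <- (max(x) - min(x)) / 1000
  si <- amo_pct / (2 * mo_s * mxdmn_s)
  list(si = si, sqrt_si = sqrt(si), mo_s = mo_s, amo_pct = amo_pct,
       mxdmn_s = mxdmn_s)
}

#' Normative values for the composite autonomic indices
#'
#' Population means and SDs used to z-score each component of the PNSi and
#' SNSi, plus the component weights.  The defaults are synthetic
#' representative values for healthy resting adults (mean RR about 900 ms,
#' RMSSD about 42 ms, resting HR about 67 bpm); they are deliberately
#' overridable and nothing in the package treats them as ground truth --
#' changing the norms shifts the indices by an affine transform and leaves
#' every correlation or regression analysis unchanged.
#'
#' @param mean_rr,rmssd,sd1_nu,mean_hr,sqrt_si,sd2_nu Length-2 numeric
#'   vectors `c(mean, sd)` per component.  `sd1_nu`/`sd2_nu` are SD1 and
#'   SD2 in normalized units, `100 * sd / (sd1 + sd2)` (percent).
#' @param weights_pnsi,weights_snsi Non-negative component weights
#'   (normalized to sum to 1) over `(mean_rr, rmssd, sd1_nu)` and
#'   `(mean_hr, sqrt_si, sd2_nu)` respectively.
#' @return A validated list of class `hrv_norms`.
#' @seealso [read_norms()] to load norms from a YAML file.
#' @export
hrv_norms <- function(mean_rr = c(900, 110), rmssd = c(42, 15),
                      sd1_nu = c(35, 10), mean_hr = c(67, 8),
                      sqrt_si = c(9, 3), sd2_nu = c(65, 10),
                      weights_pnsi = c(1, 1, 1) / 3,
                      weights_snsi = c(1, 1, 1) / 3) {
  comp <- list(mean_rr = mean_rr, rmssd = rmssd, sd1_nu = sd1_nu,
               mean_hr = mean_hr, sqrt_si = sqrt_si, sd2_nu = sd2_nu)
  for (nm in names(comp)) {
    v <- comp[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[2] <= 0)
      stop_parameter(sprintf("norm `%s` must be c(mean, sd) with sd > 0", nm))
    comp[[nm]] <- c(mean = v[1], sd = v[2])
  }
  norm_w <- function(w, name) {
    if (!is.numeric(w) || length(w) != 3L || any(w < 0) || sum(w) <= 0)
      stop_parameter(sprintf("`%s` must be 3 non-negative weights", name))
    w / sum(w)
  }
  structure(c(comp, list(weights_pnsi = norm_w(weights_pnsi, "weights_pnsi"),
                         weights_snsi = norm_w(weights_snsi, "weights_snsi"))),
            class = "hrv_norms")
}

#' Read HRV norms from a YAML file
#'
#' The file may define any subset of the [hrv_norms()] components as
#' `component: [mean, sd]` entries plus optional `weights_pnsi` /
#' `weights_snsi`; missing entries fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `hrv_norms` object.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("norms file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(hrv_norms, vals)
}

index_component <- function(value, norms, name) {
  if (is.null(value) || length(value) != 1L || !is.finite(value))
    stop_input(sprintf("component `%s` is missing or non-finite", name))
  (value - norms[[name]][["mean"]]) / norms[[name]][["sd"]]
}

#' Composite parasympathetic index (PNSi)
#'
#' Weighted sum of the z-scores (against population norms) of mean RR,
#' RMSSD and SD1 in normalized units (`100 sd1 / (sd1 + sd2)`).
#'
#' @param metrics A list (or `hrv_metrics`) containing `mean_rr`, `rmssd`,
#'   `sd1` and `sd2`.
#' @param norms An [hrv_norms()] object.
#' @return The PNSi (dimensionless).
#' @export
compute_pnsi <- function(metrics, norms = hrv_norms()) {
  stopifnot(inherits(norms, "hrv_norms"))
  sd1 <- metrics$sd1; sd2 <- metrics$sd2
  sd1_nu <- if (is.null(sd1) || is.null(sd2)) NULL else
    100 * sd1 / (sd1 + sd2)
  z <- c(index_component(metrics$mean_rr, norms, "mean_rr"),
         index_component(metrics$rmssd, norms, "rmssd"),
         index_component(sd1_nu, norms, "sd1_nu"))
  sum(norms$weights_pnsi * z)
}

#' Composite sympathetic index (SNSi)
#'
#' Weighted sum of the z-scores of mean HR, the square root of the Baevsky
#' stress index, and SD2 in normalized units (`100 sd2 / (sd1 + sd2)`).
#'
#' @inheritParams compute_pnsi
#' @param metrics A list containing `mean_hr`, `sqrt_si`, `sd1` and `sd2`.
#' @return The SNSi (dimensionless).
#' @export
compute_snsi <- function(metrics, norms = hrv_norms()) {
  stopifnot(inherits(norms, "hrv_norms"))
  sd1 <- metrics$sd1; sd2 <- metrics$sd2
  sd2_nu <- if (is.null(sd1) || is.null(sd2)) NULL else
    100 * sd2 / (sd1 + sd2)
  z <- c(index_component(metrics$mean_hr, norms, "mean_hr"),
         index_component(metrics$sqrt_si, norms, "sqrt_si"),
         index_component(sd2_nu, norms, "sd2_nu"))
  sum(norms$weights_snsi * z)
}

#' Full HRV analysis pipeline
#'
#' Deterministic composition: artifact correction, smoothness-priors
#' detrending, metric computation, composite indices.  Mean RR/HR and the
#' stress index are computed on the corrected raw series; RMSSD and
#' SD1/SD2 on the detrended series (the conventional short-term HRV
#' workflow order).  Degenerate metrics (e.g. the stress index of a
#' constant series) are set to `NA` with a warning rather than aborting
#' the subject.
#'
#' @param rr An [rr_series()].
#' @param norms An [hrv_norms()] object.
#' @param lambda Smoothness-priors regularization (default 500).
#' @param artifact_level Correction level, see [correct_artifacts()].
#' @param bin_width_ms Stress-index histogram bin width (ms).
#' @return An object of class `hrv_metrics`: list with `mean_rr`,
#'   `mean_hr`, `rmssd`, `sd1`, `sd2`, `sd1_sd2_ratio`, `baevsky_si`,
#'   `sqrt_si`, `pnsi`, `snsi`, `subject_id`, `phase`, plus the artifact
#'   correction report.
#' @examples
#' rr <- generate_rr_series(synth_config(seed = 2, duration_s = 300))
#' m <- hrv_pipeline(rr)
#' c(m$rmssd, m$pnsi, m$snsi)
#' @export
hrv_pipeline <- function(rr, norms = hrv_norms(), lambda = 500,
                         artifact_level = "medium", bin_width_ms = 50) {
  stopifnot(inherits(rr, "rr_series"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_ansflow(sprintf("[%s] %s", name, conditionMessage(e)),
                    class(e)[1])
    })
  }
  soft <- function(name, expr) {
    tryCatch(expr, ansflow_degenerate_error = function(e) {
      warning(sprintf("stage %s degenerate: %s", name, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  corrected <- stage("artifact_correction",
                     correct_artifacts(rr, level = artifact_level))
  td <- stage("time_domain", time_domain_metrics(corrected))
  det <- stage("detrend", detrend_smoothness_priors(corrected,
                                                    lambda = lambda))
  dx <- det$detrended
  d <- diff(dx)
  rmssd <- sqrt(mean(d^2))
  poin <- soft("poincare", poincare_metrics(dx + mean(corrected$rr)))
  sd1 <- sqrt(mean(d^2) / 2)
  sd2 <- if (is.null(poin)) NA_real_ else poin$sd2
  ratio <- if (is.null(poin)) NA_real_ else poin$sd1_sd2_ratio
  si <- soft("baevsky", baevsky_stress_index(corrected,
                                             bin_width_ms = bin_width_ms))
  metrics <- list(mean_rr = td$mean_rr, mean_hr = td$mean_hr, rmssd = rmssd,
                  sd1 = sd1, sd2 = sd2, sd1_sd2_ratio = ratio,
                  baevsky_si = if (is.null(si)) NA_real_ else si$si,
                  sqrt_si = if (is.null(si)) NA_real_ else si$sqrt_si)
  metrics$pnsi <- tryCatch(compute_pnsi(metrics, norms),
                           error = function(e) NA_real_)
  metrics$snsi <- tryCatch(compute_snsi(metrics, norms),
                           error = function(e) NA_real_)
  metrics$subject_id <- rr$subject_id
  metrics$phase <- rr$phase
  metrics$correction_report <- attr(corrected, "correction_report")
  class(metrics) <- "hrv_metrics"
  metrics
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf(paste0("<hrv_metrics> subject %s, phase %s\n",
                     "  mean RR %.1f ms (HR %.1f bpm), RMSSD %.2f ms\n",
                     "  SD1 %.2f, SD2 %.2f ms (ratio %.3f), SI %.1f\n",
                     "  PNSi %.3f, SNSi %.3f\n"),
              x$subject_id, x$phase, x$mean_rr, x$mean_hr, x$rmssd,
              x$sd1, x$sd2, x$sd1_sd2_ratio, x$baevsky_si, x$pnsi, x$snsi))
  invisible(x)
}
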