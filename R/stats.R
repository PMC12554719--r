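# The statistical layer: Spearman correlation with FDR correction, paired
# t-tests, one-way ANOVA, frequency-wise group comparison with contiguous
# cluster labelling, and the PF -> PNSi/SNSi regression and external
# prediction validation.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  The p-value uses the
#' exact permutation distribution for n <= 9 (no ties) and the
#' t approximation otherwise, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_size("Spearman correlation needs at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_degenerate("constant vector: Spearman rho is undefined")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = (n <= 9L && !has_ties)))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment (sort ascending, scale by `m/i`, enforce
#' monotonicity from the largest rank down, clip at 1, restore the input
#' order).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"` (Benjamini-Yekutieli).
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(pvals, method = method)
}

#' Paired t-test
#'
#' @param pre,post Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop_data("pre and post must have equal length")
  if (length(pre) < 2L) stop_size("paired t-test needs at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0)
    stop_degenerate("zero-variance differences: paired t undefined")
  tt <- tryCatch(t.test(post, pre, paired = TRUE),
                 error = function(e)
                   stop_degenerate("differences essentially constant: paired t undefined"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' One-way analysis of variance
#'
#' Classic equal-variance between/within decomposition across independent
#' groups (3 groups of 20 give df (2, 57)).
#'
#' @param groups List of numeric vectors, at least 2 groups of >= 2 values.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_data("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_data("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (all(vapply(groups, function(v) sd(v) == 0, logical(1))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L)
    stop_degenerate("no variance within or between groups: F undefined")
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

#' Frequency-wise group comparison with cluster labelling
#'
#' At every frequency of a shared grid, compares the group distributions of
#' a spectral quantity (e.g. coherence) with a one-way ANOVA; adjusts the
#' per-frequency p-values with BH-FDR over frequencies; and labels maximal
#' contiguous runs of significant frequencies as clusters.  This is a
#' frequency-wise FDR procedure with contiguity labelling, not a
#' permutation cluster-mass test.
#'
#' @param group_spectra Named list of numeric matrices, one per group, each
#'   subjects x frequencies on the same grid.
#' @param freqs Frequency grid in Hz (length = ncol of every matrix).
#' @param alpha Significance level applied to the FDR-adjusted p-values.
#' @return An object of class `freqwise_comparison`: list with `freqs`,
#'   `p_raw`, `p_fdr`, `alpha`, and `clusters` (data.frame with columns
#'   `lo_hz`, `hi_hz`, `n_bins`).
#' @export
freqwise_group_compare <- function(group_spectra, freqs, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  if (!is.list(group_spectra) || length(group_spectra) < 2L)
    stop_data("need spectra from at least 2 groups")
  mats <- lapply(group_spectra, as.matrix)
  nf <- length(freqs)
  if (any(vapply(mats, ncol, integer(1)) != nf))
    stop_data("all group matrices must share the frequency grid")
  p_raw <- vapply(seq_len(nf), function(k) {
    one_way_anova(lapply(mats, function(m) m[, k]))$p
  }, numeric(1))
  p_fdr <- fdr_adjust(p_raw)
  sig <- p_fdr < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  clusters <- data.frame(lo_hz = freqs[starts[keep]],
                         hi_hz = freqs[ends[keep]],
                         n_bins = runs$lengths[keep])
  structure(list(freqs = freqs, p_raw = p_raw, p_fdr = p_fdr,
                 alpha = alpha, clusters = clusters),
            class = "freqwise_comparison")
}

#' @export
print.freqwise_comparison <- function(x, ...) {
  cat(sprintf("<freqwise_comparison> %d frequencies, %d significant cluster(s) at alpha = %g\n",
              length(x$freqs), nrow(x$clusters), x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Linear regression of an autonomic index on PF
#'
#' Ordinary least squares of SNSi or PNSi on the coherence peak frequency,
#' with intercept.
#'
#' @param cohort A cohort `data.frame` with columns `pf` and the target
#'   column (`snsi` or `pnsi`); e.g. from [generate_cohort()] or
#'   [run_pipeline()].  Rows with missing values are dropped.
#' @param target `"snsi"` or `"pnsi"`.
#' @return An object of class `pf_regression`: list with `slope`,
#'   `intercept`, `r2`, `p_value` (two-sided slope test), `residual_sd`,
#'   `n`, `target` and the underlying `lm` fit in `model`.
#' @examples
#' fit <- fit_pf_regression(generate_cohort(cohort_spec(), seed = 1), "snsi")
#' c(fit$slope, fit$intercept, fit$r2)
#' @export
fit_pf_regression <- function(cohort, target = c("snsi", "pnsi")) {
  target <- match.arg(target)
  if (!all(c("pf", target) %in% names(cohort)))
    stop_data(sprintf("cohort must contain columns 'pf' and '%s'", target))
  d <- data.frame(pf = cohort$pf, y = cohort[[target]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3L) stop_size("regression needs at least 3 complete rows")
  if (sd(d$pf) == 0) stop_degenerate("constant PF: slope is unidentifiable")
  fit <- lm(y ~ pf, data = d)
  sm <- suppressWarnings(summary(fit))  # r2 = 1 is a legitimate input here
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 residual_sd = sm$sigma, n = nrow(d), target = target,
                 model = fit),
            class = "pf_regression")
}

#' @export
print.pf_regression <- function(x, ...) {
  cat(sprintf("<pf_regression> %s = %.3f PF %+.3f  (R2 = %.3f, p = %.3g, n = %d)\n",
              toupper(x$target), x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Predict an index from PF and validate against observations
#'
#' Applies a fitted PF regression to new PF values and compares predictions
#' with observed index values by a paired t-test, reporting the mean error
#' and 95% limits of agreement.  A non-significant paired t supports the
#' transferability of the regression to the external data.
#'
#' @param fit A `pf_regression` from [fit_pf_regression()].
#' @param pf_new New PF values (Hz).
#' @param observed Observed index values, same length as `pf_new`.
#' @return List with `predictions`, `test` (paired t result, or `NULL` if
#'   degenerate), `degenerate` flag, `mean_error` (observed - predicted)
#'   and `limits_of_agreement`.
#' @export
predict_and_validate <- function(fit, pf_new, observed) {
  stopifnot(inherits(fit, "pf_regression"))
  if (length(pf_new) == 0L || length(observed) == 0L)
    stop_input("pf_new and observed must be non-empty")
  if (length(pf_new) != length(observed))
    stop_data("pf_new and observed must have equal length")
  pred <- fit$slope * as.numeric(pf_new) + fit$intercept
  d <- as.numeric(observed) - pred
  degenerate <- (length(d) < 2L || sd(d) == 0)
  test <- if (degenerate) NULL else paired_t(pred, as.numeric(observed))
  list(predictions = pred, test = test, degenerate = degenerate,
       mean_error = mean(d),
       limits_of_agreement = mean(d) + c(-1.96, 1.96) * sd(d))
}
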