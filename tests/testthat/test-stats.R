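# The statistical layer: Spearman, FDR, paired t, ANOVA, frequency-wise
# comparison, regression and external validation.

test_that("Spearman correlation is monotone-invariant and matches enumeration", {
  x <- c(0.3, 1.1, 2.5, 3.2, 4.8, 6.1)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(x, rep(1, 6)),
               class = "ansflow_degenerate_error")

  # exact p at n = 5 against full 5! permutation enumeration
  set.seed(55)
  for (i in 1:20) {
    a <- rnorm(5)
    b <- rnorm(5)
    got <- spearman_cor(a, b)
    orc <- oracle_spearman_exact(a, b)
    expect_equal(got$rho, orc$rho, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30)
    base <- spearman_cor(x, y)
    tr <- spearman_cor(exp(x), y^3 + 5 * y)
    expect_equal(tr$rho, base$rho, tolerance = 1e-12)
    expect_equal(tr$p, base$p, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand values and the brute-force definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.04, 6)), rep(0.04, 6))
  expect_error(fdr_adjust(c(0.1, 1.2)), class = "ansflow_input_error")

  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("paired t-test matches hand arithmetic and its symmetries", {
  pre <- c(0, 0, 0)
  post <- c(1, 2, 3)
  res <- paired_t(pre, post)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)  # 3.464
  expect_equal(res$df, 2)

  flipped <- paired_t(post, pre)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p, res$p)

  set.seed(2)
  x <- rnorm(20)
  near_null <- paired_t(x, x + rnorm(20, 0, 1e-8))
  expect_lt(abs(near_null$t), 3)
  expect_error(paired_t(x, x + 1), class = "ansflow_degenerate_error")
})

test_that("one-way ANOVA has the expected structure", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(one_way_anova(g)$f, 0)

  set.seed(9)
  groups <- lapply(1:3, function(i) rnorm(20, mean = i * 0.2))
  res <- one_way_anova(groups)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 57)

  # two groups: F equals the squared pooled-variance t statistic
  a <- rnorm(15); b <- rnorm(12, 0.5)
  f2 <- one_way_anova(list(a, b))$f
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f2, unname(t2), tolerance = 1e-9)

  expect_error(one_way_anova(list(c(1, 2))), class = "ansflow_data_error")
})

test_that("frequency-wise comparison labels contiguous significant runs", {
  # deterministic p-values via constructed groups at 5 frequencies:
  # groups differ strongly at bins 2-3 only
  set.seed(14)
  freqs <- c(1.0, 1.1, 1.2, 1.3, 1.4)
  base <- matrix(rnorm(20 * 5, 0, 0.1), 20, 5)
  shifted <- base
  shifted[, 2:3] <- shifted[, 2:3] + 1
  res <- freqwise_group_compare(list(a = base + rnorm(100, 0, 0.01),
                                     b = shifted),
                                freqs, alpha = 0.05)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$lo_hz, 1.1)
  expect_equal(res$clusters$hi_hz, 1.2)
  expect_true(all(res$p_fdr[2:3] < 0.05))

  # single-frequency grid: cluster is that point or empty
  one <- freqwise_group_compare(list(a = matrix(rnorm(10), 10, 1),
                                     b = matrix(rnorm(10, 3), 10, 1)),
                                freqs = 1.2)
  expect_equal(one$clusters$lo_hz, 1.2)
  expect_equal(one$clusters$hi_hz, 1.2)

  expect_error(freqwise_group_compare(list(a = matrix(0, 3, 4),
                                           b = matrix(0, 3, 5)),
                                      freqs = 1:4),
               class = "ansflow_data_error")
})

test_that("null frequency-wise comparison rarely reports clusters", {
  set.seed(100)
  n_runs <- 40
  any_cluster <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    groups <- lapply(1:3, function(i) matrix(rnorm(10 * 32), 10, 32))
    res <- freqwise_group_compare(groups, freqs = seq_len(32) * 0.0156)
    any_cluster[r] <- nrow(res$clusters) > 0
  }
  expect_gte(mean(!any_cluster), 0.9)
})

test_that("a group-specific shared oscillator is detected as a cluster at its frequency", {
  n_seeds <- 20
  hits <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    specs <- lapply(1:3, function(g) {
      mat <- t(vapply(1:12, function(i) {
        cfg <- synth_config(seed = s * 1000 + g * 100 + i, duration_s = 120,
                            pf_target = 1.2,
                            shared_fraction = if (g == 1) 0.8 else 0)
        cs <- compute_coherence(generate_bilateral_perfusion(cfg),
                                segment_len = 1024)
        band <- cs$freqs >= 1.0 & cs$freqs <= 1.5
        cs$coherence[band]
      }, numeric(9)))
      mat
    })
    cfg0 <- synth_config(seed = 1, duration_s = 120)
    cs0 <- compute_coherence(generate_bilateral_perfusion(cfg0),
                             segment_len = 1024)
    fr <- cs0$freqs[cs0$freqs >= 1.0 & cs0$freqs <= 1.5]
    res <- freqwise_group_compare(specs, fr)
    hits[s] <- nrow(res$clusters) > 0 &&
      any(res$clusters$lo_hz - 1e-9 <= 1.2 & res$clusters$hi_hz + 1e-9 >= 1.2)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("PF regression recovers exact and noisy generating models", {
  d <- data.frame(pf = seq(1, 1.5, length.out = 10))
  d$snsi <- 2 * d$pf + 1
  fit <- fit_pf_regression(d, "snsi")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # reversed-axis slope equals 1/slope only for a perfect fit
  rev_exact <- lm(pf ~ snsi, d)
  expect_equal(unname(coef(rev_exact)[2]), 1 / fit$slope, tolerance = 1e-9)
  set.seed(20)
  d$snsi <- d$snsi + rnorm(10, 0, 0.3)
  noisy <- fit_pf_regression(d, "snsi")
  rev_noisy <- unname(coef(lm(pf ~ snsi, d))[2])
  expect_false(isTRUE(all.equal(rev_noisy, 1 / noisy$slope,
                                tolerance = 1e-3)))

  expect_error(fit_pf_regression(data.frame(pf = rep(1.2, 5),
                                            snsi = rnorm(5)), "snsi"),
               class = "ansflow_degenerate_error")
})

test_that("OLS recovers the generating coefficients within 3 standard errors", {
  spec <- cohort_spec(n_per_group = 2000, groups = "all", group_pf_shift = 0)
  co <- generate_cohort(spec, seed = 42)
  fit <- fit_pf_regression(co, "snsi")
  se <- summary(fit$model)$coefficients[, 2]
  expect_lt(abs(fit$slope - 6.48), 3 * se[2])
  expect_lt(abs(fit$intercept - -7.23), 3 * se[1])
})

test_that("external validation behaves under agreement, identity and shift", {
  spec <- cohort_spec(n_per_group = 100, groups = "all", group_pf_shift = 0)
  fit <- fit_pf_regression(generate_cohort(spec, seed = 1), "snsi")

  # observations from the same model: paired t usually non-significant
  nonsig <- vapply(1:30, function(s) {
    new <- generate_cohort(spec, seed = 1000 + s)
    predict_and_validate(fit, new$pf, new$snsi)$test$p > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)

  # exact agreement is flagged as degenerate, not tested
  new <- generate_cohort(spec, seed = 2)
  exact <- predict_and_validate(fit, new$pf,
                                fit$slope * new$pf + fit$intercept)
  expect_true(exact$degenerate)
  expect_null(exact$test)

  # a constant shift is detected
  shifted <- predict_and_validate(fit, new$pf,
                                  fit$slope * new$pf + fit$intercept + 0.5 +
                                    rnorm(nrow(new), 0, 0.1))
  expect_lt(shifted$test$p, 0.001)
  expect_equal(shifted$mean_error, 0.5, tolerance = 0.1)

  expect_error(predict_and_validate(fit, numeric(), numeric()),
               class = "ansflow_input_error")
})
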