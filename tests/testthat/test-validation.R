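test_that("percent bias follows its sign convention", {
  expect_equal(percent_bias(2, 2), 0)
  expect_equal(percent_bias(0.95, 1), -5)
  # regression-induced bias: est = 0.98 ref - 0.07 at ref = 2
  expect_equal(percent_bias(0.98 * 2 - 0.07, 2), -5.5)
  expect_lt(percent_bias(1.9, 2), 0)
  expect_warning(out <- percent_bias(1, 0), "undefined")
  expect_true(is.na(out))
})

test_that("method agreement reduces to identity on self-comparison", {
  bp <- list(s1 = c(a = 1, b = 2, c = 3, d = 4),
             s2 = c(a = 1.5, b = 2.5, c = 3.5, d = 4.5))
  groups <- c(s1 = "hc", s2 = "pd")
  ag <- method_agreement(bp, bp, groups, "self")
  expect_equal(ag$per_subject$slope, c(1, 1))
  expect_equal(ag$per_subject$intercept, c(0, 0))
  expect_equal(ag$per_subject$r_squared, c(1, 1))
  expect_equal(ag$per_subject$bias_mean, c(0, 0))
  expect_equal(unname(ag$pooled[["slope"]]), 1)
})

test_that("agreement recovers an injected multiplicative error", {
  set.seed(31)
  truth <- lapply(1:6, function(i) stats::setNames(runif(20, 0.5, 4.5),
                                                   sprintf("r%02d", 1:20)))
  names(truth) <- sprintf("s%d", 1:6)
  est <- lapply(truth, function(v) 0.95 * v)
  groups <- stats::setNames(rep(c("hc", "pd"), each = 3), names(truth))
  ag <- method_agreement(est, truth, groups, "scaled")
  expect_equal(ag$per_subject$slope, rep(0.95, 6), tolerance = 1e-10)
  expect_equal(ag$per_subject$bias_mean, rep(-5, 6), tolerance = 1e-10)
  expect_true(all(ag$per_subject$r_squared > 0.9999))
  # subjects with < 3 common regions are skipped
  est$s1 <- est$s1[1:2]
  ag2 <- method_agreement(est, truth, groups, "scaled")
  expect_equal(ag2$skipped, "s1")
})

test_that("OLS matches the closed-form normal equations", {
  set.seed(11)
  x <- rnorm(25); y <- 1.4 * x - 0.3 + rnorm(25, 0, 0.2)
  got <- refkin:::ols_line(x, y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- slope^2 * sxx / sum((y - mean(y))^2)
  expect_equal(got[["slope"]], slope, tolerance = 1e-10)
  expect_equal(got[["intercept"]], intercept, tolerance = 1e-10)
  expect_equal(got[["r_squared"]], r2, tolerance = 1e-10)
})

test_that("Welch test matches the hand formula and its conventions", {
  hc <- c(1.1, 1.4, 0.9)
  pd <- c(1.8, 2.1, 1.7, 2.4, 1.9)
  got <- group_ttest(hc, pd)
  s1 <- var(hc) / 3; s2 <- var(pd) / 5
  tstat <- (mean(hc) - mean(pd)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / 2 + s2^2 / 4)
  expect_equal(got$t, tstat, tolerance = 1e-10)
  expect_equal(got$df, df, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-10)

  # identical degenerate groups: p = 1 by convention
  expect_equal(group_ttest(c(1, 1, 1), c(1, 1))$p_value, 1)
  expect_error(group_ttest(1, c(1, 2)), "at least 2")

  # strong separation is detected in (almost) every replicate
  hits <- sum(vapply(1:100, function(i) {
    set.seed(i)
    group_ttest(rnorm(10, 0, 1), rnorm(10, 5, 1))$p_value < 0.001
  }, TRUE))
  expect_gte(hits, 99)
})

test_that("time stability is flat at zero for noiseless data", {
  sd <- oracle_subject_data(6)
  rep80 <- time_stability(sd, run_config(methods = "SRTM2-pop",
                                         k2_prime = 0.037),
                          t_max_grid = c(40, 80))
  b <- rep80$bias
  # self-reference: full-length bias is exactly zero
  expect_true(all(b$bias_pct[b$t_max == 120] == 0))
  # noiseless stability for t_max >= 40
  expect_lt(max(abs(b$bias_pct[b$t_max == 80])), 1)
  expect_lt(max(abs(b$bias_pct[b$t_max == 40])), 2)
  # t_max beyond scan end is skipped with a flag
  rep2 <- time_stability(sd, run_config(methods = "SRTM2-pop",
                                        k2_prime = 0.037),
                         t_max_grid = c(80, 150))
  expect_equal(rep2$skipped_t_max, 150)
  sm <- summarize_time_stability(list(rep80))
  expect_true(all(c("bias_mean", "abs_bias_mean") %in% names(sm)))
})
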