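test_that("exact permutation Spearman reproduces small-sample p-values", {
  # n = 7, sum of squared rank differences 4
  res <- spearman_test(1:7, c(2, 1, 3, 4, 5, 7, 6))
  expect_equal(res$method, "exact_permutation")
  expect_equal(res$sum_d2, 4L)
  expect_equal(res$rho, 1 - 6 * 4 / (7 * 48))
  expect_equal(res$p_two_sided, 34 / 5040)

  # identity ranking: only identity and full reversal reach |rho| = 1
  res_id <- spearman_test(1:7, 1:7)
  expect_equal(res_id$rho, 1)
  expect_equal(res_id$p_two_sided, 2 / 5040)

  # n = 3 with one adjacent swap: every permutation has |rho| >= 0.5
  res3 <- spearman_test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res3$rho, 0.5)
  expect_equal(res3$p_two_sided, 1)

  expect_error(spearman_test(1:2, 2:1), "n >= 3")
})

test_that("exact enumeration agrees with independent oracles", {
  set.seed(61)
  for (n in 4:6) {
    x <- rnorm(n)
    y <- rnorm(n)
    res <- spearman_test(x, y)
    expect_equal(res$p_two_sided, naive_exact_spearman_p(x, y))
  }
  # strongly correlated n = 7 data: both tail regions are disjoint, so the
  # doubled-tail convention of cor.test coincides with the |rho| count
  x <- 1:7
  y <- c(1, 2, 4, 3, 5, 7, 6)
  res <- spearman_test(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(res$p_two_sided, ct$p.value)
})

test_that("t-approximation reproduces the large-sample printed p-value", {
  # build tie-free data with rho ~ 0.745 at n = 17; check the closed form
  rho <- 0.745; n <- 17
  t_expected <- rho * sqrt((n - 2) / (1 - rho^2))
  p_expected <- 2 * pt(-t_expected, n - 2)
  expect_equal(p_expected, 0.00059, tolerance = 0.02)

  set.seed(3)
  x <- 1:17
  y <- rank(x + rnorm(17, 0, 4.5))
  res <- spearman_test(x, y, exact_limit = 9)
  expect_equal(res$method, "t_approximation")
  expect_equal(res$df, 15L)
  expect_equal(res$p_two_sided,
               2 * pt(-abs(res$rho * sqrt(15 / (1 - res$rho^2))), 15))
})

test_that("exact and t-approximate p broadly agree at n = 9", {
  rel <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(9); y <- rnorm(9)
    e <- spearman_test(x, y, exact_limit = 9)$p_two_sided
    t <- spearman_test(x, y, exact_limit = 0)$p_two_sided
    abs(e - t) / e
  }, numeric(1))
  # tail p-values (where the t-approximation is anti-conservative) may
  # stray further; bulk agreement is tight
  expect_gte(mean(rel <= 0.25), 0.95)
  expect_true(all(rel <= 0.40))
})

test_that("ties force the t-approximation and rho is monotone-invariant", {
  x <- c(1, 2, 2, 4, 5, 6, 7)
  y <- c(2, 1, 4, 3, 6, 5, 7)
  expect_warning(res <- spearman_test(x, y), "ties")
  expect_equal(res$method, "t_approximation")

  set.seed(77)
  a <- runif(12); b <- runif(12)
  r1 <- suppressWarnings(spearman_test(a, b))
  r2 <- suppressWarnings(spearman_test(exp(3 * a), b^3 + 5))
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
})

test_that("log-log calibration recovers exact and generated power laws", {
  f <- c(1, 10, 100, 1000)
  m <- fit_calibration(f, 2 * f)
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, log10(2))
  expect_equal(fit_calibration(f, rep(5, 4))$slope, 0)
  expect_error(fit_calibration(c(1, 0, 3), c(1, 2, 3)), "positive")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")

  g <- generate_synthetic(generator_config(seed = 7))
  expr <- fpkm(g$counts, g$annotation)
  rec <- g$ish$gene_ids
  x <- expr$mean_fpkm[rec]
  y <- g$ish$mean_per_section[rec]
  pos <- x > 0 & y > 0
  fitg <- fit_calibration(x[pos], y[pos])
  expect_lt(abs(fitg$slope - 1), 0.15)
})

test_that("predictions follow the fitted line and are monotone", {
  m <- structure(list(slope = 1, intercept = 0), class = "calibration_model")
  expect_equal(predict_cells(m, 10), 10)
  f <- c(2, 5, 20, 80)
  fit <- fit_calibration(f, 3 * f^0.8)
  expect_equal(predict_cells(fit, f[2]),
               10^(fit$intercept + fit$slope * log10(f[2])))
  preds <- predict_cells(fit, c(1, 10, 100))
  expect_true(all(diff(preds) >= 0))
  expect_error(predict_cells(fit, 0), "positive")
})

test_that("total cell estimates are floored products", {
  expect_equal(estimate_total_cells(89.1, 10), 891L)
  expect_equal(estimate_total_cells(0.5, 500), 250L)
  expect_equal(estimate_total_cells(3, 0), 0L)
  expect_error(estimate_total_cells(-1, 5), "non-negative")
})

test_that("synthetic FPKM rank-tracks true neuron counts", {
  g <- generate_synthetic(generator_config(seed = 1))
  expr <- fpkm(g$counts, g$annotation)
  rec <- names(g$truth$neuron_counts)
  rho <- cor(expr$mean_fpkm[rec], g$truth$neuron_counts, method = "spearman")
  expect_gte(rho, 0.9)
})
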