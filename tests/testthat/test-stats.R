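test_that("paired comparison matches exact enumeration and flags degeneracy", {
  pre <- c(10, 11, 12, 13, 14)
  post <- pre + c(1, 2, 3, 4, 5)
  res <- compare_paired(pre, post)
  w <- res[res$method == "wilcoxon signed-rank", ]
  expect_equal(w$p_value, 1 / 16)                      # 2^5 sign patterns
  expect_equal(w$p_value, wilcoxon_exact_p(post - pre))
  t <- res[res$method == "paired t", ]
  expect_equal(t$p_value, stats::t.test(post, pre, paired = TRUE)$p.value)
  # all ties: Wilcoxon undefined, flagged
  tied <- compare_paired(pre, pre)
  expect_true(all(tied$flagged))
  expect_true(all(is.na(tied$p_value)))
  # zero-variance nonzero differences: t degenerate, flagged
  res2 <- compare_paired(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(res2$flagged[res2$method == "paired t"])
})

test_that("Mann-Whitney exact enumeration oracle agreement at small n", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$estimate, 0)                         # U for first group
  expect_equal(res$p_value, 0.1)                        # 2/C(6,3)
  expect_equal(res$p_value, mann_whitney_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # approximation tracks the enumeration oracle over seeded datasets
  set.seed(19)
  gaps <- replicate(100, {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    approx_p <- compare_groups(a, b, exact_max = 0)$p_value
    abs(approx_p - mann_whitney_exact_p(a, b))
  })
  expect_lt(max(gaps), 0.02)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney type-I error is calibrated at the 5% level", {
  set.seed(23)
  rejections <- replicate(2000, {
    compare_groups(rnorm(12), rnorm(12))$p_value < 0.05
  })
  expect_equal(mean(rejections), 0.05, tolerance = 0.02 / 0.05)
})

test_that("correlations: perfect monotonicity, limits, partials", {
  mono <- correlate(1:8, (1:8)^3, method = "spearman")
  expect_equal(mono$estimate, 1)
  expect_lt(mono$p_value, 0.05)
  set.seed(3)
  x <- rnorm(50); y <- -x + rnorm(50, 0, 1e-8)
  expect_equal(correlate(x, y, method = "pearson")$estimate, -1,
               tolerance = 1e-6)
  # covariates orthogonal to x and y leave the correlation unchanged
  n <- 64
  x <- rep(c(-1, 1), n / 2); y <- rep(c(-1, -1, 1, 1), n / 4)
  z <- rep(c(-1, 1, 1, -1, 1, -1, -1, 1), n / 8)   # orthogonal contrast
  plain <- correlate(x, y, method = "pearson")
  part <- correlate(x, y, method = "pearson", covariates = cbind(z))
  expect_equal(part$estimate, plain$estimate, tolerance = 1e-6)
  expect_true(correlate(rep(1, 10), rnorm(10))$flagged)
  expect_error(correlate(1:3, 1:3), "n >= 4")
})

test_that("partial Spearman agrees with rank-residual computation", {
  set.seed(44)
  n <- 40
  age <- rnorm(n); x <- rnorm(n) + 0.5 * age; y <- rnorm(n) - 0.3 * age
  res <- correlate(x, y, method = "spearman", covariates = cbind(age))
  rx <- stats::resid(stats::lm(rank(x) ~ age))
  ry <- stats::resid(stats::lm(rank(y) ~ age))
  expect_equal(res$estimate, stats::cor(rx, ry))
})

test_that("logistic treatment model: null calibration and recovery", {
  set.seed(101)
  null_p <- replicate(100, {
    dt1 <- rnorm(500, -0.13, 0.05)
    tx <- runif(500) < 0.6
    tidy(fit_treatment_logistic(dt1, tx))$p_value[2]
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  # parameter recovery at beta1 = 10
  set.seed(102)
  dt1 <- rnorm(2000, -0.13, 0.2)
  eta <- 2 + 10 * dt1
  tx <- runif(2000) < stats::plogis(eta)
  fit <- fit_treatment_logistic(dt1, tx)
  b1 <- tidy(fit)$estimate[2]
  expect_lt(abs(b1 - 10) / 10, 0.25)
  # phenotype adjustment adds a third coefficient
  ph <- sample(c("RRMS", "PMS"), 2000, replace = TRUE)
  fit2 <- fit_treatment_logistic(dt1, tx, phenotype = ph)
  expect_identical(nrow(tidy(fit2)), 3L)
  expect_error(fit_treatment_logistic(rnorm(10), rep(TRUE, 10)), "classes")
  # perfect separation is flagged, coefficients withheld
  sep <- fit_treatment_logistic(c(-1, -1, -1, 1, 1, 1) * 0.2,
                                c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_false(sep$converged)
  expect_identical(nrow(tidy(sep)), 0L)
})

test_that("FDR adjustment: hand-computed case, monotone, idempotent", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(14)
  p <- runif(30)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_identical(order(adj[order(p)]), seq_along(p))  # order preserved
  expect_true(all(fdr_adjust(adj) >= adj))              # re-adjusting never lowers
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("EDSS dichotomisation splits at the sample median", {
  g <- edss_dichotomize(c(1, 2, 3, 4, 6.5))
  expect_identical(as.character(g),
                   c("<=median", "<=median", "<=median", ">median", ">median"))
})
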