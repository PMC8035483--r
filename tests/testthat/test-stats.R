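test_that("cognitive-status classification uses the strict MoCA cutoff", {
  expect_equal(classify_cognitive_status(25), "CI")
  expect_equal(classify_cognitive_status(26), "NCI")
  expect_equal(classify_cognitive_status(30), "NCI")
  expect_equal(classify_cognitive_status(c(0, 25, 26)), c("CI", "CI", "NCI"))
  expect_error(classify_cognitive_status(31), "0..30")
})

test_that("chi-square test reproduces the published sex-composition p", {
  res <- chi_square_test(rbind(c(23, 13), c(20, 10), c(30, 18)))
  expect_equal(res$df, 2)
  expect_lt(abs(res$p - 0.933), 0.005)
  # identical row proportions: statistic 0, p 1
  res0 <- chi_square_test(rbind(c(10, 5), c(20, 10)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  res2 <- chi_square_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("summary t tests reproduce the published clinical comparisons", {
  # pooled
  expect_lt(abs(two_sample_t_from_summary(36, 764.40, 229.66,
                                          30, 714.62, 182.45,
                                          "pooled")$p - 0.340), 0.005)
  expect_lt(abs(two_sample_t_from_summary(36, 30.42, 9.63,
                                          30, 29.77, 7.95,
                                          "pooled")$p - 0.769), 0.005)
  # Welch
  expect_lt(abs(two_sample_t_from_summary(36, 83.66, 17.52,
                                          30, 95.22, 22.78,
                                          "welch")$p - 0.027), 0.005)
  # equal means
  eq <- two_sample_t_from_summary(10, 5, 1, 12, 5, 1.2, "pooled")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # agreement with t.test on raw data summarised
  set.seed(1)
  a <- rnorm(14); b <- rnorm(17, 0.4)
  raw <- t.test(a, b, var.equal = TRUE)
  smry <- two_sample_t_from_summary(14, mean(a), sd(a), 17, mean(b), sd(b),
                                    "pooled")
  expect_lt(abs(smry$p - raw$p.value), 1e-10)
  raw_w <- t.test(a, b)
  smry_w <- two_sample_t_from_summary(14, mean(a), sd(a), 17, mean(b), sd(b),
                                      "welch")
  expect_lt(abs(smry_w$p - raw_w$p.value), 1e-10)
})

test_that("summary ANOVA reproduces the published age comparison", {
  res <- one_way_anova_from_summary(list(c(36, 31.19, 7.90),
                                         c(30, 31.33, 7.09),
                                         c(48, 31.93, 7.99)))
  expect_lt(abs(res$p - 0.896), 0.005)
  expect_equal(res$df, c(2, 111))
  # all means equal
  eq <- one_way_anova_from_summary(list(c(10, 2, 1), c(12, 2, 2)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # two groups: F equals the square of the pooled t
  tt <- two_sample_t_from_summary(14, 3.1, 1.2, 17, 2.5, 0.9, "pooled")
  ff <- one_way_anova_from_summary(list(c(14, 3.1, 1.2), c(17, 2.5, 0.9)))
  expect_lt(abs(ff$statistic - tt$statistic^2), 1e-10)
  # agreement with aov on raw data summarised
  set.seed(2)
  g <- rep(1:3, c(9, 11, 10))
  y <- rnorm(30) + 0.3 * g
  sm <- t(sapply(split(y, g), function(v) c(length(v), mean(v), sd(v))))
  raw_p <- summary(aov(y ~ factor(g)))[[1]]$`Pr(>F)`[1]
  expect_lt(abs(one_way_anova_from_summary(sm)$p - raw_p), 1e-10)
})

test_that("ANCOVA reduces to ANOVA without covariates and matches an
           explicit least-squares oracle", {
  set.seed(3)
  g <- factor(rep(c("A", "B", "C"), each = 8))
  y <- rnorm(24) + c(0, 0.5, 1)[as.integer(g)]
  a1 <- ancova_group_test(y, g)
  raw <- summary(aov(y ~ g))[[1]]
  expect_lt(abs(a1$statistic - raw$`F value`[1]), 1e-10)
  expect_lt(abs(a1$p - raw$`Pr(>F)`[1]), 1e-12)

  # covariates orthogonal to group and response absorb no sum of squares:
  # the group effect (extra SS over residual SS) is unchanged, and the F
  # statistics agree exactly once the residual degrees of freedom consumed
  # by the inert covariates are accounted for
  covs <- cbind(qr.Q(qr(matrix(rnorm(48), 24)))[, 1:2])
  covs <- covs - rowsum(covs, g)[g, ] / 8   # centre within group
  resid_y <- lm.fit(cbind(1, covs), y)$residuals
  a2 <- ancova_group_test(resid_y, g, covs)
  a3 <- ancova_group_test(resid_y, g)
  expect_lt(abs(a2$statistic / a2$df[2] - a3$statistic / a3$df[2]), 1e-8)

  # 12-row worked data set against a normal-equations oracle
  y12 <- c(3.1, 2.9, 3.5, 4.0, 4.4, 4.1, 5.0, 5.2, 4.8, 3.9, 4.2, 4.6)
  g12 <- factor(rep(c("A", "B", "C"), each = 4))
  c12 <- cbind(age = c(21, 25, 30, 28, 35, 22, 27, 31, 24, 29, 33, 26))
  res <- ancova_group_test(y12, g12, c12)
  x_full <- cbind(1, c12, g12 == "B", g12 == "C")
  x_red <- cbind(1, c12)
  rss <- function(x) {
    beta <- solve(t(x) %*% x, t(x) %*% y12)
    sum((y12 - x %*% beta)^2)
  }
  f_oracle <- ((rss(x_red) - rss(x_full)) / 2) / (rss(x_full) / (12 - 4))
  expect_lt(abs(res$statistic - f_oracle), 1e-8)
  expect_equal(res$df, c(2, 8))
  # Bonferroni post hoc caps at 1 and multiplies by 3
  expect_true(all(res$posthoc$p_adjusted <= 1))
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p - 1e-15))
  expect_equal(res$posthoc$p_adjusted,
               pmin(1, 3 * res$posthoc$p))
})

test_that("partial correlation test residualises and reduces correctly", {
  set.seed(4)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  r0 <- partial_correlation_test(x, y)
  expect_equal(r0$r, cor(x, y), tolerance = 1e-12)
  expect_lt(abs(r0$p - cor.test(x, y)$p.value), 1e-10)
  # y identical to x: r = 1 regardless of covariates
  r1 <- partial_correlation_test(x, x, cbind(rnorm(50)))
  expect_equal(r1$r, 1)
  # a shared covariate removes all association; with y equal to the
  # covariate exactly the residual is constant, which is an error
  n <- 10000
  cvar <- rnorm(n)
  expect_error(partial_correlation_test(rnorm(n), cvar, cbind(cvar)),
               "constant")
  y_c <- cvar + 0.1 * rnorm(n)
  r2 <- partial_correlation_test(rnorm(n), y_c, cbind(cvar))
  expect_lt(abs(r2$r), 0.03)
  expect_error(partial_correlation_test(rep(1, 20), rnorm(20)), "constant")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(bh_fdr(rep(0.05, 8)), rep(0.05, 8))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
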