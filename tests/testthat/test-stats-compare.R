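test_that("paired t-test handles the documented trivial cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_t_one_tailed(x, x, "less")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
  # constant nonzero differences: zero SD handled as +/- Inf
  res2 <- paired_t_one_tailed(x, x + 1, "greater")
  expect_equal(res2$t, Inf)
  expect_lt(res2$p, 0.005)
  expect_error(paired_t_one_tailed(1:4, 1:5), class = "gaitvar_pairing_error")
  expect_error(paired_t_one_tailed(1:2, 2:3),
               class = "gaitvar_insufficient_data_error")
})

test_that("one-tailed p is half the two-tailed p on the hypothesized side", {
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- a - abs(rnorm(10, 0.5, 0.2))  # b < a
    one <- paired_t_one_tailed(a, b, "less")
    two <- paired_t_one_tailed(a, b, "two.sided")
    expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  }
})

test_that("paired t has nominal type-I error under the null", {
  set.seed(7)
  rej <- mean(replicate(2000, {
    a <- rnorm(10); b <- rnorm(10)
    paired_t_one_tailed(a, b, "less")$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Wilcoxon signed-rank reproduces exact reference values", {
  a <- 1:10
  b <- a - seq(0.5, 5, by = 0.5)   # all ON < OFF
  res <- wilcoxon_signed_rank(a, b, "less")
  expect_equal(unname(res$V), 0)
  expect_equal(res$p, 1 / 1024)
  # one discordant pair with the smallest absolute difference
  b2 <- b
  b2[1] <- a[1] + 0.1
  res2 <- wilcoxon_signed_rank(a, b2, "less")
  expect_equal(unname(res2$V), 1)
  expect_error(wilcoxon_signed_rank(a, a), class = "gaitvar_degenerate_error")
})

test_that("Wilcoxon exact p matches 2^n brute-force enumeration", {
  set.seed(8)
  for (n in c(6, 9, 12)) {
    for (rep in 1:5) {
      a <- rnorm(n)
      b <- a + rnorm(n)  # continuous: no ties, no zeros
      for (dir in c("less", "greater")) {
        res <- wilcoxon_signed_rank(a, b, dir)
        expect_equal(res$p, brute_force_signed_rank_p(b - a, dir),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Wilcoxon type-I error under the null is controlled", {
  set.seed(9)
  rej <- mean(replicate(2000, {
    a <- rnorm(10); b <- rnorm(10)
    wilcoxon_signed_rank(a, b, "less")$p < 0.05
  }))
  expect_lte(rej, 0.065)
})

test_that("assumption checks behave as documented", {
  set.seed(10)
  # equal variances: Bartlett K2 near 0 on identical spread
  a <- rnorm(50); b <- sample(a)
  expect_lt(variance_check(a, b)$K2, 1e-10)
  expect_error(normality_check(rep(1, 10)), class = "gaitvar_degenerate_error")
  expect_error(variance_check(rep(1, 5), rep(2, 5)),
               class = "gaitvar_degenerate_error")
  # Shapiro-Wilk near-uniform rejection rate on Normal data
  rej <- mean(replicate(500, normality_check(rnorm(500))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # Bartlett power: 9x variance ratio detected most of the time
  pow <- mean(replicate(500, {
    variance_check(rnorm(10, sd = 3), rnorm(10, sd = 1))$p < 0.05
  }))
  expect_gte(pow, 0.8)
})

test_that("two-group MANOVA reproduces the protocol degrees of freedom", {
  set.seed(11)
  res <- manova_two_group(matrix(rnorm(100), 10, 10),
                          matrix(rnorm(100), 10, 10))
  expect_equal(res$df1, 10)
  expect_equal(res$df2, 9)
  expect_gt(res$lambda, 0)
  expect_lte(res$lambda, 1)
})

test_that("Wilks' Lambda matches the eigenvalue oracle and stats::manova", {
  set.seed(12)
  for (p in 1:3) {
    n <- 12
    xa <- matrix(rnorm(n * p), n, p)
    xb <- matrix(rnorm(n * p, mean = 0.5), n, p)
    res <- manova_two_group(xa, xb)
    # oracle 1: Lambda = prod(1 / (1 + eig(E^-1 H)))
    m1 <- colMeans(xa); m2 <- colMeans(xb); m <- (m1 + m2) / 2
    H <- n * tcrossprod(m1 - m) + n * tcrossprod(m2 - m)
    E <- crossprod(sweep(xa, 2, m1)) + crossprod(sweep(xb, 2, m2))
    lam_eig <- prod(1 / (1 + Re(eigen(solve(E, H))$values)))
    expect_equal(res$lambda, lam_eig, tolerance = 1e-9)
    if (p >= 2) {
      # oracle 2: stats::manova Wilks (needs multiple responses)
      g <- factor(rep(c("a", "b"), each = n))
      y <- rbind(xa, xb)
      fit <- summary(stats::manova(y ~ g), test = "Wilks")
      expect_equal(res$lambda, fit$stats[1, "Wilks"], tolerance = 1e-9)
      expect_equal(res$F, fit$stats[1, "approx F"], tolerance = 1e-9)
    }
  }
})

test_that("for p = 1 the MANOVA F is the squared two-sample t", {
  set.seed(13)
  xa <- matrix(rnorm(10), 10, 1)
  xb <- matrix(rnorm(10, 1), 10, 1)
  res <- manova_two_group(xa, xb)
  tt <- t.test(xa, xb, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("MANOVA limits and errors", {
  set.seed(14)
  # identical group means with tiny within-group noise: Lambda -> 1, F -> 0
  base <- matrix(rnorm(20), 10, 2)
  res <- manova_two_group(base + 1e-9 * matrix(rnorm(20), 10, 2),
                          base + 1e-9 * matrix(rnorm(20), 10, 2))
  expect_gt(res$lambda, 0.999)
  # rank-deficient within-group matrix
  dup <- matrix(rnorm(10), 10, 1)[, c(1, 1)]
  expect_error(manova_two_group(dup, dup + 1), class = "gaitvar_rank_error")
  # paired Hotelling variant needs n >= p + 1
  expect_error(manova_two_group(matrix(rnorm(50), 5, 10),
                                matrix(rnorm(50), 5, 10), mode = "paired"),
               "n >= p")
})

test_that("bonferroni_threshold is alpha/m", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("identical profiles fail the MANOVA gate and skip point tests", {
  set.seed(15)
  off <- make_profiles(rep(0.005, 10), condition = "OFF")
  res <- compare_conditions(off, transform(off, condition = "ON"))
  expect_false(res$gate_passed)
  expect_true(all(is.na(res$points$p)))
  expect_false(any(res$points$significant))
  expect_equal(res$threshold, 0.005)
  expect_equal(res$m, 10)
})

test_that("mismatched participants or grids raise pairing errors", {
  set.seed(16)
  off <- make_profiles(rep(0.005, 10), condition = "OFF")
  on <- make_profiles(rep(0.005, 10), condition = "ON",
                      participants = sprintf("Q%02d", 1:10))
  expect_error(compare_conditions(off, on), class = "gaitvar_pairing_error")
  on2 <- make_profiles(rep(0.005, 10), condition = "ON",
                       phases = full_cycle_grid())
  expect_error(compare_conditions(off, on2), class = "gaitvar_pairing_error")
})

test_that("the gated protocol detects a 0.8x reduction most of the time", {
  set.seed(17)
  levels_off <- c(1, 1.4, 2.2, 3.5, 4.9, 6.2, 7.5, 8.8, 8.8, 5.5) / 1000
  hits <- replicate(100, {
    off <- make_profiles(levels_off, condition = "OFF")
    on <- make_profiles(0.8 * levels_off, condition = "ON")
    res <- compare_conditions(off, on, direction = "less")
    res$gate_passed && any(res$points$significant)
  })
  expect_gte(mean(hits), 0.5)
})

test_that("type-I error of the gated protocol stays below the nominal level", {
  set.seed(18)
  n_rep <- 2000
  rejections <- replicate(n_rep, {
    off <- make_profiles(rep(0.005, 10), condition = "OFF")
    on <- make_profiles(rep(0.005, 10), condition = "ON")
    res <- compare_conditions(off, on, direction = "less")
    sum(res$points$significant)
  })
  per_point_rate <- sum(rejections) / (n_rep * 10)
  # nominal per-point level is alpha/m = 0.005; the gate makes the
  # protocol conservative. Allow 3 Monte-Carlo binomial SDs.
  tol <- 3 * sqrt(0.005 * 0.995 / (n_rep * 10))
  expect_lte(per_point_rate, 0.005 + tol)
})

test_that("tidy, glance and print expose the decision trace", {
  set.seed(19)
  levels_off <- seq(2, 9, length.out = 10) / 1000
  off <- make_profiles(levels_off, condition = "OFF")
  on <- make_profiles(0.7 * levels_off, condition = "ON")
  res <- compare_conditions(off, on)
  td <- tidy(res)
  expect_setequal(td$phase, swing_grid())
  expect_true(all(td$test %in% c("t", "wilcoxon") | is.na(td$test)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("lambda", "F", "df1", "df2", "p", "gate_passed",
                    "threshold") %in% names(gl)))
  expect_output(print(res), "MANOVA gate")
  expect_equal(nrow(res$assumptions), 10)
})
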