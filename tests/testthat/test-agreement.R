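test_that("Bland-Altman bias and limits follow the closed forms", {
  same <- paired_measurements(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- bland_altman(same)
  expect_equal(r$mean_difference, 0)
  expect_equal(r$sd_difference, 0)

  a <- c(-430, -450, -470, -410)
  off <- bland_altman(paired_measurements(a, a + 19))
  expect_equal(off$mean_difference, -19)
  expect_equal(off$sd_difference, 0)
  expect_equal(off$lower_limit, -19)
  expect_equal(off$upper_limit, -19)

  set.seed(12)
  x <- rnorm(10, -450, 30); y <- x + rnorm(10, 5, 12)
  got <- bland_altman(paired_measurements(x, y))
  want <- bland_altman_oracle(x, y)
  expect_equal(got$mean_difference, want$mean_difference, tolerance = 1e-12)
  expect_equal(got$sd_difference, want$sd_difference, tolerance = 1e-12)
  expect_equal(got$lower_limit, want$lower_limit, tolerance = 1e-12)
  expect_equal(got$upper_limit, want$upper_limit, tolerance = 1e-12)
  # limits symmetric about the bias, at 2 SD exactly
  expect_equal(got$upper_limit - got$mean_difference,
               got$mean_difference - got$lower_limit, tolerance = 1e-12)
  expect_equal(got$measurement_error, got$sd_difference)
})

test_that("limits of agreement cover about 95% of large Gaussian samples", {
  set.seed(13)
  x <- rnorm(4000); y <- x + rnorm(4000, 0, 5)
  r <- bland_altman(paired_measurements(x, y))
  d <- x - y
  coverage <- mean(d >= r$lower_limit & d <= r$upper_limit)
  # +/- 2 SD covers ~95.45% in the limit; binomial 3-sigma band at n = 4000
  expect_gt(coverage, 0.9545 - 3 * sqrt(0.9545 * 0.0455 / 4000))
  expect_lt(coverage, 0.9545 + 3 * sqrt(0.9545 * 0.0455 / 4000))
})

test_that("Pearson correlation handles perfect relations and matches summation", {
  a <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(paired_measurements(a, 2 * a + 5)), 1)
  expect_equal(pearson_r(paired_measurements(a, -a)), -1)
  set.seed(14)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_r(paired_measurements(x, y)), pearson_oracle(x, y),
               tolerance = 1e-12)
  expect_error(pearson_r(paired_measurements(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")
})

test_that("ICC(2,1) rewards absolute agreement and penalizes bias", {
  a <- c(-430, -450, -470, -410, -500)
  expect_equal(icc_agreement(paired_measurements(a, a)), 1)
  p_off <- paired_measurements(a, a + 19)
  expect_lt(icc_agreement(p_off), pearson_r(p_off))
  expect_message(val <- icc_agreement(paired_measurements(rep(3, 4), rep(3, 4))),
                 "convention")
  expect_equal(val, 1)
})

test_that("with exactly matched method moments ICC(2,1) equals r*n/(n-1+r)", {
  # derived by expanding the two-way mean squares when the two methods have
  # identical means and variances: MSC = 0, MSR = s^2(1+r), MSE = s^2(1-r)
  set.seed(15)
  for (n in c(6, 12, 40)) {
    a <- rnorm(n)
    b <- rnorm(n)
    b <- (b - mean(b)) / sd(b) * sd(a) + mean(a)  # force equal moments
    p <- paired_measurements(a, b)
    r <- pearson_r(p)
    expect_equal(icc_agreement(p), r * n / (n - 1 + r), tolerance = 1e-6)
  }
})

test_that("ICC estimates recover the generating variance ratio in simulation", {
  set.seed(16)
  sig_s <- 2; sig_r <- 0.5; sig_e <- 0.5
  target <- sig_s^2 / (sig_s^2 + sig_r^2 + sig_e^2)
  est <- replicate(300, {
    subj <- rnorm(10, 0, sig_s)
    rater <- rnorm(2, 0, sig_r)
    icc_agreement(paired_measurements(subj + rater[1] + rnorm(10, 0, sig_e),
                                      subj + rater[2] + rnorm(10, 0, sig_e)))
  })
  expect_lt(abs(mean(est) - target), 0.05)
})

test_that("Spearman correlation uses midranks and is monotone-invariant", {
  x <- c(2, 5, 7, 11, 13, 20)
  expect_equal(spearman_rank(x, x^3)$rho, 1)
  expect_equal(spearman_rank(x, -sqrt(x))$rho, -1)
  set.seed(17)
  xt <- c(1, 2, 2, 3, 4, 4); yt <- c(5, 5, 7, 8, 8, 9)  # ties in both
  expect_equal(spearman_rank(xt, yt)$rho, spearman_oracle(xt, yt),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms of either input
  x2 <- rnorm(8); y2 <- rnorm(8)
  base <- spearman_rank(x2, y2)
  expect_equal(spearman_rank(exp(x2), y2)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_rank(x2, y2^3)$p_value, base$p_value, tolerance = 1e-12)
  expect_error(spearman_rank(rep(1, 5), rnorm(5)), "constant")
})

test_that("rank-sum U follows the rank definition and its symmetry identities", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$u_statistic, 0)
  set.seed(18)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(7)
    ua <- rank_sum_test(a, b)$u_statistic
    ub <- rank_sum_test(b, a)$u_statistic
    expect_equal(ua + ub, 35)                     # U_a + U_b = n_a * n_b
    expect_equal(rank_sum_test(b, a)$p_value, rank_sum_test(a, b)$p_value)
    expect_equal(rank_sum_test(exp(a), exp(b))$p_value,
                 rank_sum_test(a, b)$p_value)      # monotone-invariant
  }
  expect_error(rank_sum_test(numeric(0), c(1, 2)), "nonempty")
})

test_that("exact rank-sum p-values agree with full enumeration at n = 4 + 4", {
  set.seed(19)
  for (i in 1:5) {
    a <- round(rnorm(4), 4); b <- round(rnorm(4, 0.5), 4)
    got <- rank_sum_test(a, b)
    want <- mann_whitney_exact_oracle(a, b)
    expect_true(got$exact)
    expect_equal(got$u_statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})
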