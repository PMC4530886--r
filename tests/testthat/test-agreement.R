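test_that("contingency counts partition the trials", {
  ct <- contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  ct2 <- contingency(c(1, 0, 1), c(1, 0, 1))
  expect_equal(ct2$b + ct2$c, 0)
  set.seed(41)
  for (r in 1:20) {
    pa <- rbinom(50, 1, 0.6); pb <- rbinom(50, 1, 0.4)
    ct <- contingency(pa, pb)
    # brute-force count
    cnt <- c(0, 0, 0, 0)
    for (i in 1:50) {
      if (pa[i] == 1 && pb[i] == 1) cnt[1] <- cnt[1] + 1
      if (pa[i] == 1 && pb[i] == 0) cnt[2] <- cnt[2] + 1
      if (pa[i] == 0 && pb[i] == 1) cnt[3] <- cnt[3] + 1
      if (pa[i] == 0 && pb[i] == 0) cnt[4] <- cnt[4] + 1
    }
    expect_equal(unname(unlist(ct[c("a", "b", "c", "d")])), cnt)
    expect_equal(ct$n, 50)
  }
})

test_that("categorical indices evaluate their defining formulas", {
  # perfect agreement
  r <- categorical_agreement(contingency(rep(1, 10), rep(1, 10)))
  expect_equal(r$p_o, 100)
  # a=10, d=10 perfect split
  r <- categorical_agreement(contingency(c(rep(1, 10), rep(0, 10)),
                                         c(rep(1, 10), rep(0, 10))))
  expect_equal(r$p_o, 100)
  expect_equal(r$kappa, 1)
  # complete disagreement: raw kappa -1, floored to 0
  r <- categorical_agreement(contingency(c(rep(1, 10), rep(0, 10)),
                                         c(rep(0, 10), rep(1, 10))))
  expect_equal(r$p_o, 0)
  expect_equal(r$p_e, 50)
  expect_equal(r$kappa_raw, -1)
  expect_equal(r$kappa, 0)
  # a=45, b=5, c=5, d=45
  pa <- c(rep(1, 50), rep(0, 50))
  pb <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))
  r <- categorical_agreement(contingency(pa, pb))
  expect_equal(r$p_o, 90)
  expect_equal(r$p_e, 50)
  expect_equal(r$kappa, 0.8)
  expect_equal(r$p_pos, 90)
  expect_equal(r$p_neg, 90)
  # degenerate marginals: everything positive -> p_e = 100, kappa missing,
  # p_neg undefined
  r <- categorical_agreement(contingency(rep(1, 8), rep(1, 8)))
  expect_true(is.na(r$kappa))
  expect_true(is.na(r$p_neg))
  expect_equal(r$p_pos, 100)
})

test_that("indices are invariant under swapping the two methods", {
  set.seed(43)
  for (r in 1:20) {
    pa <- rbinom(40, 1, 0.7); pb <- rbinom(40, 1, 0.5)
    r1 <- categorical_agreement(contingency(pa, pb))
    r2 <- categorical_agreement(contingency(pb, pa))
    for (f in c("p_o", "p_pos", "p_neg", "p_e", "kappa"))
      expect_equal(r1[[f]], r2[[f]])
  }
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(bland_altman(x, y)$bias, bland_altman(y, x)$bias)
  expect_equal(cv_within_pairs(x, y), cv_within_pairs(y, x))
})

test_that("paired feature series select both-present trials only", {
  set.seed(44)
  a <- random_detection_table(40)
  b <- random_detection_table(40)
  pr <- paired_feature_series(a, b, "N2", "amplitude")
  both <- which(a$n2_pres == 1 & b$n2_pres == 1)
  expect_equal(pr$n_pairs, length(both))
  expect_equal(pr$x, a$n2_amp[both])
  expect_equal(pr$y, b$n2_amp[both])
  # no common present trials -> empty
  a0 <- a; a0$p2_pres[] <- 0L
  expect_equal(paired_feature_series(a0, b, "P2", "latency")$n_pairs, 0)
  # all present in both -> n_pairs = N
  a1 <- a; a1$n1_pres[] <- 1L; a1$n1_amp[] <- -1; a1$n1_lat[] <- 90
  b1 <- b; b1$n1_pres[] <- 1L; b1$n1_amp[] <- -2; b1$n1_lat[] <- 95
  expect_equal(paired_feature_series(a1, b1, "N1", "amplitude")$n_pairs, 40)
})

test_that("Bland-Altman reproduces hand-computed values", {
  x <- c(1, 2, 3)
  ba <- bland_altman(x, c(0, 0, 0))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, 0.04)
  expect_equal(ba$loa_upper, 3.96)
  expect_equal(ba$loa, 3.96)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, 0)
  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(2, 2))
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("difference SD recovers sqrt(2) x the per-method error SD", {
  set.seed(45)
  n <- 10000
  s <- rnorm(n, 0, 5)
  sigma <- 1.5
  x <- s + rnorm(n, 0, sigma)
  y <- s + rnorm(n, 0, sigma)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$sd_diff - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.05)
})

test_that("ICC(A,1) matches the aov oracle and its analytic limits", {
  x <- c(1, 2, 3, 5)
  expect_equal(icc_single_absolute(x, x), 1)
  x0 <- c(-2, -1, 1, 2)
  expect_lte(icc_single_absolute(x0, -x0), 0)
  expect_true(is.na(icc_single_absolute(rep(1, 5), rep(1, 5))))
  set.seed(46)
  for (r in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(icc_single_absolute(x, y), oracle_icc_aov(x, y),
                 tolerance = 1e-10)
  }
})

test_that("ICC recovers the theoretical variance ratio on a subject-effect model", {
  set.seed(47)
  n <- 5000
  sb <- rnorm(n, 0, 2) # trial-level true signal, var 4
  x <- sb + rnorm(n, 0, 1)
  y <- sb + rnorm(n, 0, 1)
  # theoretical ICC = var_signal / (var_signal + var_error) = 4/5
  expect_lt(abs(icc_single_absolute(x, y) - 0.8), 0.02)
})

test_that("within-pair CV follows the RMS formula and is scale invariant", {
  expect_equal(cv_within_pairs(c(9), c(11)), 100 * sqrt(2) / 10)
  x <- runif(20, 5, 20); y <- runif(20, 5, 20)
  expect_equal(cv_within_pairs(x, y), cv_within_pairs(3.7 * x, 3.7 * y))
  expect_equal(cv_within_pairs(x, x), 0)
  # negative amplitudes give positive denominators
  expect_equal(cv_within_pairs(-x, -y), cv_within_pairs(x, y))
  expect_warning(out <- cv_within_pairs(c(0, 9), c(0, 11)), "dropped")
  expect_equal(out, 100 * sqrt(2) / 10)
  expect_warning(all_na <- cv_within_pairs(0, 0), "dropped")
  expect_true(is.na(all_na))
})

test_that("agreement_indices assembles all nine indices per peak", {
  set.seed(48)
  a <- random_detection_table(60)
  b <- random_detection_table(60)
  ai <- agreement_indices(a, b)
  expect_equal(sort(unique(ai$index)),
               sort(c("p_o", "p_pos", "p_neg", "p_e", "kappa",
                      "bias", "loa", "icc", "cv")))
  expect_equal(nrow(ai), 3 * (5 + 2 * 4))
  k <- ai$value[ai$index == "kappa"]
  expect_true(all(k >= 0 & k <= 1, na.rm = TRUE))
})
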