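fs_test <- 256

test_that("Morlet power scales quadratically and peaks at the input frequency", {
  wc <- wavelet_config(freqs = seq(2, 20, by = 1))
  n <- 512
  t <- (0:(n - 1)) / fs_test
  zeromap <- morlet_cwt(numeric(n), fs_test, wc)
  expect_true(all(zeromap$power == 0))

  x <- sin(2 * pi * 10 * t)
  m1 <- morlet_cwt(x, fs_test, wc)
  m2 <- morlet_cwt(2 * x, fs_test, wc)
  expect_equal(m2$power, 4 * m1$power, tolerance = 1e-12)
  # frequency of maximal time-averaged power is 10 Hz on a grid containing it
  mid <- 100:400
  avg_pw <- rowMeans(m1$power[, mid])
  expect_equal(m1$freqs[which.max(avg_pw)], 10)

  expect_error(morlet_cwt(x, fs_test, wavelet_config(freqs = c(5, 200))),
               "Nyquist")
})

test_that("CWT coefficients are linear in the input", {
  wc <- wavelet_config(freqs = seq(2, 20, by = 2))
  n <- 256
  set.seed(8)
  x <- rnorm(n); y <- rnorm(n)
  wx <- morlet_cwt(x, fs_test, wc)$coef
  wy <- morlet_cwt(y, fs_test, wc)$coef
  wxy <- morlet_cwt(3 * x - 2 * y, fs_test, wc)$coef
  expect_equal(wxy, 3 * wx - 2 * wy, tolerance = 1e-9)
})

test_that("average-power masks nest with threshold and match the elementwise rule", {
  set.seed(12)
  n <- 128
  wc <- wavelet_config(freqs = seq(2, 20, by = 2))
  maps <- lapply(1:4, function(i) morlet_cwt(rnorm(n), fs_test, wc))
  m_lo <- average_power_mask(maps, 0.1)
  m_hi <- average_power_mask(maps, 0.2)
  expect_true(all(m_lo[m_hi])) # mask(0.2) subset of mask(0.1)
  # elementwise oracle
  avg <- (maps[[1]]$power + maps[[2]]$power + maps[[3]]$power +
          maps[[4]]$power) / 4
  want <- matrix(FALSE, nrow(avg), ncol(avg))
  for (i in seq_len(nrow(avg))) for (j in seq_len(ncol(avg)))
    want[i, j] <- avg[i, j] >= 0.1 * max(avg)
  expect_identical(unname(m_lo), want)
  # idempotent under re-application
  expect_identical(average_power_mask(list(avg * 1), 0.1), m_lo)
  # single noiseless map at low threshold covers the global power maximum
  erp <- 10 * exp(-((0:(n - 1)) / fs_test - 0.25)^2 / (2 * 0.05^2))
  me <- morlet_cwt(erp, fs_test, wc)
  msk <- average_power_mask(list(me), 0.1)
  expect_true(msk[which.max(rowSums(me$power)),
                  which.max(colSums(me$power))])
  expect_error(average_power_mask(list(avg, avg[-1, ])), "mismatching axes")
})

test_that("mask filtering reconstructs through the inverse transform", {
  wc <- wavelet_config()
  n <- 512
  tm <- seq(-200, 1800, by = 1000 / fs_test)[1:n]
  erp <- -12 * exp(-(tm - 90)^2 / (2 * 17^2)) +
          18 * exp(-(tm - 250)^2 / (2 * 51^2))
  nf <- length(wc$freqs)
  expect_equal(filter_trial(erp, fs_test, matrix(FALSE, nf, n), wc),
               numeric(n))
  y <- filter_trial(erp, fs_test, matrix(TRUE, nf, n), wc)
  expect_gt(cor(y, erp), 0.99)
  expect_lt(abs(max(y) / max(erp) - 1), 0.1)
  expect_error(filter_trial(erp, fs_test, matrix(TRUE, 3, 3), wc),
               "mask axes")
})

test_that("an ERP-support mask raises the SNR of noisy trials", {
  set.seed(14)
  wc <- wavelet_config()
  n <- 512
  tm <- seq(-200, 1800, by = 1000 / fs_test)[1:n]
  clean <- -12 * exp(-(tm - 90)^2 / (2 * 17^2)) -
            10 * exp(-(tm - 140)^2 / (2 * 21^2)) +
            18 * exp(-(tm - 250)^2 / (2 * 51^2))
  support <- average_power_mask(list(morlet_cwt(clean, fs_test, wc)), 0.01)
  snr <- function(x) max(abs(x[tm > 0 & tm < 400])) / sd(x[tm < 0])
  ratios <- replicate(20, {
    noisy <- clean + fft_lowpass_noise(n)
    snr(filter_trial(noisy, fs_test, support, wc)) / snr(noisy)
  })
  expect_gt(mean(ratios), 1)
  expect_gte(mean(ratios > 1), 0.7)
})

test_that("regressor segments follow the zero-crossing structure", {
  n <- 400
  tm <- seq(0, n - 1) * 2 # 2 ms steps, 0..798 ms
  avg <- -10 * exp(-(tm - 115)^2 / (2 * 30^2)) +
          14 * exp(-(tm - 250)^2 / (2 * 45^2))
  rs <- build_regressors(avg, tm, c(N1 = 90, N2 = 140, P2 = 250))
  # N regressor supported only where the average is negative
  wN1 <- rs$A$design[, "N1_w"]
  expect_true(all(wN1[avg > 0] == 0))
  expect_true(all(wN1[wN1 != 0] < 0))
  # shared negative segment: N1 and N2 waveform regressors coincide here
  expect_equal(rs$A$design[, "N1_w"], rs$B$design[, "N2_w"],
               ignore_attr = TRUE)
  # P2 regressors identical across passes
  expect_equal(rs$A$design[, "P2_w"], rs$B$design[, "P2_w"],
               ignore_attr = TRUE)
  # segment boundaries equal a brute-force zero-crossing scan (the positive
  # segment containing 250 ms runs to the end of the epoch: no crossing after)
  scan <- which(avg > 0 & tm > 150)
  expect_equal(unname(rs$A$segments$P2), range(scan))
  expect_error(build_regressors(avg, tm, c(N1 = 250, N2 = NA, P2 = NA)),
               "wrong polarity")
})

test_that("least-squares fitting matches the normal equations", {
  n <- 300
  tm <- seq(0, n - 1)
  avg <- -8 * exp(-(tm - 100)^2 / (2 * 20^2)) +
          12 * exp(-(tm - 220)^2 / (2 * 30^2))
  rs <- build_regressors(avg, tm, c(N1 = 100, N2 = NA, P2 = 220))
  X <- rs$A$design
  # trial equal to 2x the waveform regressor
  fit <- fit_trial(2 * X[, "N1_w"], rs$A)
  expect_equal(unname(fit$coefficients["N1_w"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["N1_d"]), 0, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # noise orthogonal to the design projects to ~zero coefficients
  set.seed(17)
  e <- rnorm(n)
  e_orth <- e - X %*% qr.coef(qr(X), e)
  fit0 <- fit_trial(as.numeric(e_orth), rs$A)
  expect_lt(max(abs(fit0$coefficients)), 1e-8)
  # random trials: coefficients equal the normal-equation brute force
  for (r in 1:10) {
    y <- rnorm(n)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    fit <- fit_trial(y, rs$A)
    expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  }
  # rank-deficient design is reported
  rs_bad <- rs$A
  rs_bad$design <- cbind(rs$A$design, N1_w2 = rs$A$design[, "N1_w"])
  expect_error(fit_trial(rnorm(n), rs_bad), "collinear")
  expect_error(fit_trial(rnorm(10), rs$A), "time axis")
})

test_that("windowed read-off matches a brute-force scan and the polarity rule", {
  n <- 512
  tm <- seq(-200, 1800, by = 1000 / fs_test)[1:n]
  bump <- 9 * exp(-(tm - 250)^2 / (2 * 40^2))
  pk <- extract_peak(bump, tm, "P2", 250, 100)
  expect_equal(pk$present, 1L)
  expect_lt(abs(pk$latency - 250), 1000 / fs_test)
  # fitted trace non-positive in the window -> absent
  pk0 <- extract_peak(-bump, tm, "P2", 250, 100)
  expect_equal(pk0$present, 0L)
  expect_true(is.na(pk0$amplitude))
  expect_error(extract_peak(bump, tm, "P2", 1780, 100), "outside the epoch")
  set.seed(23)
  for (r in 1:50) {
    y <- random_trace(n)
    got <- extract_peak(y, tm, "N1", 90, 50)
    win <- which(tm >= 40 & tm <= 140)
    neg <- win[y[win] < 0]
    if (length(neg) == 0) {
      expect_equal(got$present, 0L)
    } else {
      i <- neg[which.min(y[neg])]
      expect_equal(got$latency, tm[i])
      expect_equal(got$amplitude, y[i])
    }
  }
})

test_that("full pipeline recovers truth on noiseless all-present studies", {
  sim <- simulate_study(noiseless_config(n_subjects = 2,
                                         n_trials_per_intensity = 2,
                                         all_present = TRUE, seed = 7))
  # threshold 0.005: the recovery scenario needs a mask that passes the
  # complete (noise-free) signal support; the default 5% power mask is a
  # denoiser that deliberately discards low-power structure
  wv <- detect_study_wvlt(sim$epochs, wavelet_config(threshold = 0.005))
  tru <- truth_detection_tables(sim$truth)
  for (s in names(wv)) {
    d <- wv[[s]]; tt <- tru[[s]]
    expect_true(all(d$n1_pres == 1 & d$n2_pres == 1 & d$p2_pres == 1))
    laterr <- abs(cbind(d$n1_lat - tt$n1_lat, d$n2_lat - tt$n2_lat,
                        d$p2_lat - tt$p2_lat))
    expect_lt(max(laterr), 5)
    relamp <- abs(cbind(d$n1_amp / tt$n1_amp, d$n2_amp / tt$n2_amp,
                        d$p2_amp / tt$p2_amp) - 1)
    expect_lt(max(relamp), 0.1)
  }
})

test_that("two-pass separation yields distinct N1/N2 estimates without a zero crossing", {
  sim <- simulate_study(noiseless_config(n_subjects = 1,
                                         n_trials_per_intensity = 2,
                                         all_present = TRUE, seed = 19))
  e <- sim$epochs[[1]]
  # the default templates produce an N1-N2 complex with no zero crossing
  avg <- colMeans(e$traces)
  between <- avg[e$time_ms > 95 & e$time_ms < 135]
  expect_true(all(between < 0))
  wv <- detect_study_wvlt(sim$epochs, wavelet_config(threshold = 0.005))[[1]]
  expect_true(all(wv$n1_pres == 1 & wv$n2_pres == 1))
  expect_true(all(wv$n2_lat - wv$n1_lat > 20))
})
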