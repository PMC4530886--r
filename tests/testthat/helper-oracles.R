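# Independent brute-force oracles used to cross-check the implementation.
# These are written as literal, loop-based transcriptions of the rules and
# share no code with the package internals.

# Extrema by explicit neighbour comparison; plateaus contribute their
# midpoint sample.
oracle_extrema <- function(v) {
  n <- length(v)
  out <- data.frame(index = integer(0), type = character(0))
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] == v[i - 1L]) { i <- i + 1L; next }
    j <- i
    while (j < n && v[j + 1L] == v[j]) j <- j + 1L
    if (j >= n) break
    if (v[i] > v[i - 1L] && v[i] > v[j + 1L])
      out <- rbind(out, data.frame(index = as.integer(floor((i + j) / 2)),
                                   type = "max"))
    if (v[i] < v[i - 1L] && v[i] < v[j + 1L])
      out <- rbind(out, data.frame(index = as.integer(floor((i + j) / 2)),
                                   type = "min"))
    i <- j + 1L
  }
  out
}

# Literal transcription of the DRIV selection rules: quadratic weights,
# weighted-magnitude scoring with sign admissibility, earlier-latency ties,
# closest-center resolution of a shared N1/N2 minimum with re-search, and
# the final N1-before-N2 ordering convention.
oracle_driv <- function(trace, time_ms, zones) {
  ext <- oracle_extrema(trace)
  wfun <- function(lat, z) {
    if (lat <= z$lower || lat >= z$upper) return(0)
    b <- if (lat < z$center) z$lower else z$upper
    max(0, 1 - ((lat - z$center) / (b - z$center))^2)
  }
  cands <- function(z, exclude = integer(0)) {
    want <- if (z$polarity < 0) "min" else "max"
    rows <- list()
    for (r in seq_len(nrow(ext))) {
      if (ext$type[r] != want) next
      idx <- ext$index[r]
      if (idx %in% exclude) next
      lat <- time_ms[idx]
      amp <- trace[idx]
      w <- wfun(lat, z)
      if (w > 0 && sign(amp) == z$polarity)
        rows[[length(rows) + 1L]] <- c(idx = idx, lat = lat, amp = amp,
                                       score = abs(amp) * w)
    }
    if (length(rows) == 0) return(NULL)
    do.call(rbind, rows)
  }
  top <- function(cc) {
    if (is.null(cc)) return(NULL)
    best <- cc[cc[, "score"] == max(cc[, "score"]), , drop = FALSE]
    best[which.min(best[, "lat"]), ]
  }
  sel <- list(N1 = top(cands(zones$N1)), N2 = top(cands(zones$N2)),
              P2 = top(cands(zones$P2)))
  if (!is.null(sel$N1) && !is.null(sel$N2) &&
      sel$N1[["idx"]] == sel$N2[["idx"]]) {
    lat <- sel$N1[["lat"]]
    keep <- if (abs(lat - zones$N1$center) <= abs(lat - zones$N2$center))
      "N1" else "N2"
    oth <- setdiff(c("N1", "N2"), keep)
    sel[[oth]] <- top(cands(zones[[oth]], exclude = sel[[keep]][["idx"]]))
  }
  if (!is.null(sel$N1) && !is.null(sel$N2) &&
      sel$N1[["lat"]] > sel$N2[["lat"]]) {
    tmp <- sel$N1; sel$N1 <- sel$N2; sel$N2 <- tmp
  }
  g <- function(p, f) if (is.null(p)) NA_real_ else p[[f]]
  list(n1 = c(pres = as.integer(!is.null(sel$N1)), lat = g(sel$N1, "lat"),
              amp = g(sel$N1, "amp")),
       n2 = c(pres = as.integer(!is.null(sel$N2)), lat = g(sel$N2, "lat"),
              amp = g(sel$N2, "amp")),
       p2 = c(pres = as.integer(!is.null(sel$P2)), lat = g(sel$P2, "lat"),
              amp = g(sel$P2, "amp")))
}

# ICC(A,1) through an independent two-way ANOVA decomposition via stats::aov.
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  df <- data.frame(value = c(x, y),
                   trial = factor(rep(seq_len(n), 2)),
                   method = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(value ~ trial + method, data = df))[[1]]
  ms <- tab[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Random smooth traces for detector cross-checks.
random_trace <- function(n, smooth = 5) {
  x <- cumsum(rnorm(n))
  if (smooth > 1) x <- as.numeric(stats::filter(x, rep(1 / smooth, smooth),
                                                sides = 2))
  x[is.na(x)] <- 0
  x - mean(x)
}

default_test_zones <- function() {
  list(N1 = fuzzy_zone("N1", 90, 55, 125),
       N2 = fuzzy_zone("N2", 140, 105, 175),
       P2 = fuzzy_zone("P2", 250, 180, 320))
}

# Random detection tables (for I/O and agreement plumbing tests).
random_detection_table <- function(n_trials, intensities = rep(1:6, length.out = n_trials)) {
  pres <- function() rbinom(n_trials, 1, 0.7)
  p1 <- pres(); p2 <- pres(); p3 <- pres()
  detection_table(
    trial = seq_len(n_trials),
    n1_lat = ifelse(p1 == 1, runif(n_trials, 60, 120), NA),
    n2_lat = ifelse(p2 == 1, runif(n_trials, 120, 180), NA),
    p2_lat = ifelse(p3 == 1, runif(n_trials, 200, 320), NA),
    n1_amp = ifelse(p1 == 1, -runif(n_trials, 5, 30), NA),
    n2_amp = ifelse(p2 == 1, -runif(n_trials, 5, 30), NA),
    p2_amp = ifelse(p3 == 1, runif(n_trials, 5, 40), NA),
    n1_pres = p1, n2_pres = p2, p2_pres = p3,
    intensity = intensities)
}

# Small noiseless study configurations used across detector tests.
noiseless_config <- function(n_subjects = 2, n_trials_per_intensity = 3,
                             all_present = FALSE, seed = 42) {
  pt <- default_peak_templates()
  pt$lat_sd <- 0
  pt$amp_sd <- 0
  if (all_present) pt$pres_mid <- -10 # presence probability ~1 everywhere
  sim_config(n_subjects = n_subjects,
             n_trials_per_intensity = n_trials_per_intensity,
             noise_sd = 0, peak_templates = pt, seed = seed)
}

# Band-limited background noise for SNR experiments (AR(1) coloured noise).
fft_lowpass_noise <- function(n, sd_target = 8) {
  x <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  x <- x / stats::sd(x) * sd_target
  x - mean(x)
}
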