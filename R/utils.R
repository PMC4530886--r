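# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
time_axis <- function(window_ms, fs) {
  n <- round(diff(window_ms) * fs / 1000)
  window_ms[1] + (seq_len(n) - 1) * 1000 / fs
}

# Nearest sample index for a latency in ms.
#' @noRd
lat_index <- function(time_ms, lat) which.min(abs(time_ms - lat))

# Zero-phase band-pass via the squared Butterworth magnitude response applied
# in the frequency domain (equivalent to forward-backward IIR filtering but
# numerically stable at very low normalized cutoffs). The demeaned signal is
# extended by even reflection before the FFT so the periodic extension has no
# step discontinuity at the epoch edges. `low = 0` disables the high-pass
# branch (the mean is then restored), `high = Inf` the low-pass branch.
#' @noRd
fft_bandpass <- function(x, fs, low, high, order = 4L) {
  n <- length(x)
  xm <- mean(x)
  xe <- c(x - xm, rev(x - xm))
  m <- length(xe)
  xf <- stats::fft(xe)
  k <- 0:(m - 1)
  f <- ifelse(k <= m / 2, k, k - m) * fs / m
  af <- abs(f)
  h <- rep(1, m)
  if (high < Inf) h <- h / (1 + (af / high)^(2 * order))
  if (low > 0) {
    hp <- numeric(m)
    nz <- af > 0
    hp[nz] <- 1 / (1 + (low / af[nz])^(2 * order))
    h <- h * hp
  }
  y <- Re(stats::fft(xf * h, inverse = TRUE))[seq_len(n)] / m
  if (low <= 0) y <- y + xm
  y
}

# Small deterministic polynomial hash of a character scalar, reported as hex.
# Used to stamp output tables with a configuration fingerprint.
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Format numeric columns with full (round-trip) precision for CSV export so
# that write -> read preserves doubles exactly and outputs are byte-stable.
#' @noRd
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
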