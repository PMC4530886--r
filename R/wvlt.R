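# WVLT: single-trial ERP estimation by Morlet-wavelet denoising followed by
# multiple linear regression. Trials are mapped to the time-frequency plane
# with a complex Morlet CWT, the across-trial mean power is thresholded into a
# binary mask, each trial is reconstructed from its masked coefficients, and
# peak amplitudes/latencies are read off a least-squares fit of each filtered
# trial against regressors derived from the filtered average ERP.

#' Wavelet analysis configuration
#'
#' @param f_b Morlet bandwidth parameter.
#' @param f_0 Morlet center-frequency parameter.
#' @param freqs Analysis frequencies in Hz. The default is a log-spaced grid
#'   from 0.25 to 30 Hz with 16 voices per octave: log spacing keeps the
#'   density of wavelet kernels proportional to their bandwidth (which scales
#'   with frequency), so the inverse transform has a flat amplitude response
#'   across the band, and the low edge sits well below the band so that wide,
#'   low-frequency peaks are reconstructed without amplitude loss.
#' @param threshold Binary-mask threshold as a fraction of the maximum of the
#'   across-trial mean power.
#' @param readoff_halfwidth Named half-widths (ms) of the read-off windows
#'   centred on each average-ERP peak latency. The N1/N2 defaults (25 ms) are
#'   deliberately smaller than the N1-N2 separation (~50 ms): a window that
#'   spans both negative peaks reads off whichever is deeper, so the window
#'   must not reach the neighbouring peak.
#' @param analysis_rate Internal sampling rate in Hz; epochs are low-pass
#'   filtered and decimated to this rate before the CWT (all analysis content
#'   lies below 30 Hz).
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(f_b = 0.05, f_0 = 6,
                           freqs = 0.25 * 2^(seq(0, log2(30 / 0.25), by = 1 / 16)),
                           threshold = 0.05,
                           readoff_halfwidth = c(N1 = 25, N2 = 25, P2 = 100),
                           analysis_rate = 256) {
  stopifnot(f_b > 0, f_0 > 0, all(freqs > 0), threshold > 0, threshold < 1)
  structure(list(f_b = f_b, f_0 = f_0, freqs = sort(freqs),
                 threshold = threshold,
                 readoff_halfwidth = readoff_halfwidth,
                 analysis_rate = analysis_rate),
            class = "wavelet_config")
}

# Precomputed filter bank: FFT-domain Morlet kernels at each analysis
# frequency plus delta-reconstruction weights and the calibration constant.
#
# The analytic Morlet wavelet used here is
#   psi(t) = (pi f_b)^(-1/2) exp(2 pi i f_0 t) exp(-t^2 / f_b),
# whose Fourier transform is exp(-pi^2 f_b (f - f_0)^2). The kernel for
# analysis frequency fk is the L2-normalised dilation with scale a = f_0 / fk.
# Reconstruction uses the single-integral (delta) formula
#   x(t) ~= C * sum_k w_k Re W(fk, t),  w_k = dln(f)_k * sqrt(fk),
# with C calibrated so that the bank's response to an in-band sinusoid is 1
# (the response has the closed form 0.5 * sum_k w_k sqrt(a_k)
# exp(-pi^2 f_b (a_k f - f_0)^2), evaluated at mid-band frequencies).
#' @noRd
morlet_bank <- function(fs, n, config) {
  freqs <- config$freqs
  if (any(freqs >= fs / 2))
    stop("analysis frequencies must lie below the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  npad <- 2L^ceiling(log2(2L * n))
  k <- 0:(npad - 1)
  f <- ifelse(k <= npad / 2, k, k - npad) * fs / npad
  a <- config$f_0 / freqs
  G <- matrix(0, nrow = length(freqs), ncol = npad)
  for (j in seq_along(freqs)) {
    ex <- -pi^2 * config$f_b * (a[j] * f - config$f_0)^2
    G[j, ] <- sqrt(a[j]) * exp(pmax(ex, -745))
  }
  lf <- log(freqs)
  dln <- diff(lf)
  dln <- c(dln[1], (dln[-length(dln)] + dln[-1]) / 2, dln[length(dln)])
  w <- dln * sqrt(freqs)
  gain_at <- function(fq) {
    0.5 * sum(w * sqrt(a) * exp(pmax(-pi^2 * config$f_b * (a * fq - config$f_0)^2, -745)))
  }
  interior <- freqs[freqs >= 4 * min(freqs) & freqs <= max(freqs) / 4]
  C <- 1 / stats::median(vapply(interior, gain_at, numeric(1)))
  list(freqs = freqs, G = G, w = w, C = C, n = n, npad = npad, fs = fs)
}

#' @noRd
bank_cwt <- function(trace, bank) {
  X <- stats::fft(c(trace, numeric(bank$npad - bank$n)))
  W <- matrix(0i, nrow = length(bank$freqs), ncol = bank$n)
  for (j in seq_along(bank$freqs)) {
    W[j, ] <- stats::fft(X * bank$G[j, ], inverse = TRUE)[seq_len(bank$n)] / bank$npad
  }
  W
}

#' @noRd
bank_icwt <- function(W, bank) {
  bank$C * as.numeric(crossprod(Re(W), bank$w))[seq_len(bank$n)]
}

#' Continuous Morlet wavelet transform of one trace
#'
#' @param trace Voltage series.
#' @param fs Sampling rate in Hz.
#' @param config A [wavelet_config()].
#' @param time_ms Optional time axis stored with the map.
#' @return A list of class `tf_map` with complex `coef` (frequency x time),
#'   `power` (squared magnitude), `freqs`, `time_ms` and `fs`.
#' @export
morlet_cwt <- function(trace, fs, config = wavelet_config(),
                       time_ms = seq_along(trace)) {
  stopifnot(all(is.finite(trace)))
  bank <- morlet_bank(fs, length(trace), config)
  W <- bank_cwt(trace, bank)
  structure(list(coef = W, power = Mod(W)^2, freqs = bank$freqs,
                 time_ms = time_ms, fs = fs), class = "tf_map")
}

#' Binary mask from the across-trial mean power
#'
#' `mask[i, j]` is `TRUE` where the mean power reaches at least
#' `threshold * max(mean power)`. Raising the threshold never adds cells.
#'
#' @param tf_maps List of `tf_map` objects (or of plain power matrices with
#'   identical dimensions).
#' @param threshold Fraction of the maximum mean power.
#' @return Logical matrix (frequency x time).
#' @export
average_power_mask <- function(tf_maps, threshold = 0.05) {
  stopifnot(length(tf_maps) >= 1)
  pw <- lapply(tf_maps, function(m) if (inherits(m, "tf_map")) m$power else m)
  dims <- vapply(pw, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("time-frequency maps have mismatching axes", call. = FALSE)
  avg <- Reduce(`+`, pw) / length(pw)
  avg >= threshold * max(avg)
}

#' Filter one trial through a binary time-frequency mask
#'
#' Computes the trial's Morlet coefficients, zeroes the coefficients outside
#' the mask, and reconstructs the time-domain trace with the inverse
#' transform. With an all-ones mask the reconstruction reproduces the
#' band-limited input (calibrated unit gain); with an all-zero mask the output
#' is zero.
#'
#' @param trace Voltage series.
#' @param fs Sampling rate in Hz.
#' @param mask Logical matrix from [average_power_mask()] (frequency x time,
#'   matching the trial's CWT grid).
#' @param config A [wavelet_config()].
#' @return Filtered voltage series, same length as `trace`.
#' @export
filter_trial <- function(trace, fs, mask, config = wavelet_config()) {
  bank <- morlet_bank(fs, length(trace), config)
  if (!all(dim(mask) == c(length(bank$freqs), bank$n)))
    stop("mask axes do not match the trial's time-frequency grid", call. = FALSE)
  W <- bank_cwt(trace, bank)
  W[!mask] <- 0i
  bank_icwt(W, bank)
}

#' Build regression passes from the filtered average ERP
#'
#' The filtered average is split at its zero crossings; each peak's waveform
#' regressor is the average restricted to the segment containing that peak's
#' latency (zero elsewhere) and its derivative regressor is the first
#' difference of the waveform regressor. Because vertex N1 and N2 usually share
#' one negative segment without a zero crossing between them, regressors are
#' arranged in two passes, each holding one negative peak together with P2:
#' pass A = \{N1, P2\}, pass B = \{N2, P2\}.
#'
#' @param filtered_avg Filtered average ERP.
#' @param time_ms Time axis (ms).
#' @param peak_latencies Named vector with elements `N1`, `N2`, `P2` (ms);
#'   `NA` drops the peak from its pass.
#' @return List of two passes (`A`, `B`); each pass has `peaks`, `design`
#'   (columns `<peak>_w`, `<peak>_d`) and `segments` (per-peak index ranges).
#' @export
build_regressors <- function(filtered_avg, time_ms, peak_latencies) {
  n <- length(filtered_avg)
  s <- sign(filtered_avg)
  # zeros inherit the previous (else next) nonzero sign so segments are
  # maximal runs of constant polarity
  nz <- s != 0
  if (any(nz)) {
    filled <- s
    last <- 0
    for (i in seq_len(n)) {
      if (filled[i] == 0) filled[i] <- last else last <- filled[i]
    }
    nxt <- 0
    for (i in rev(seq_len(n))) {
      if (filled[i] == 0) filled[i] <- nxt else nxt <- filled[i]
    }
    s <- filled
  }
  seg_id <- cumsum(c(1L, as.integer(s[-1] != s[-n])))

  one_peak <- function(pk) {
    lat <- peak_latencies[[pk]]
    if (is.null(lat) || is.na(lat)) return(NULL)
    pol <- if (grepl("^N", pk)) -1 else 1
    i <- lat_index(time_ms, lat)
    if (s[i] != pol)
      stop("latency of ", pk, " (", lat,
           " ms) falls on a segment of the wrong polarity", call. = FALSE)
    in_seg <- seg_id == seg_id[i]
    wv <- ifelse(in_seg, filtered_avg, 0)
    dv <- c(0, diff(wv))
    m <- cbind(wv, dv)
    colnames(m) <- paste0(pk, c("_w", "_d"))
    list(design = m, segment = range(which(in_seg)))
  }

  mk_pass <- function(label, pks) {
    parts <- Filter(Negate(is.null), lapply(pks, one_peak))
    if (length(parts) == 0) return(NULL)
    design <- do.call(cbind, lapply(parts, `[[`, "design"))
    segs <- lapply(parts, `[[`, "segment")
    names(segs) <- substr(colnames(design)[seq(1, ncol(design), 2)], 1, 2)
    list(pass = label, peaks = names(segs), design = design, segments = segs)
  }
  list(A = mk_pass("A", c("N1", "P2")), B = mk_pass("B", c("N2", "P2")))
}

#' Least-squares fit of a filtered trial against a regressor pass
#'
#' @param filtered_trial Filtered single-trial voltage series.
#' @param regressors One pass from [build_regressors()].
#' @return List with `coefficients`, `fitted` and `residuals`.
#' @export
fit_trial <- function(filtered_trial, regressors) {
  design <- regressors$design
  if (nrow(design) != length(filtered_trial))
    stop("regressors and trial do not share the time axis", call. = FALSE)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop("rank-deficient regressor design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qd, filtered_trial)
  fitted <- as.numeric(design %*% beta)
  list(coefficients = beta, fitted = fitted,
       residuals = filtered_trial - fitted)
}

#' Read one peak off a fitted trace
#'
#' The amplitude is the extremum of the peak's polarity within a window
#' centred on the average-ERP latency; the latency is its time. The peak is
#' absent when no sample of the correct polarity exists in the window.
#'
#' @param fitted Fitted voltage series.
#' @param time_ms Time axis (ms).
#' @param peak Peak label (`"N1"`, `"N2"`, `"P2"`).
#' @param avg_latency Window center in ms.
#' @param halfwidth Window half-width in ms (defaults from
#'   [wavelet_config()]).
#' @return List with `present` (0/1), `amplitude` and `latency`.
#' @export
extract_peak <- function(fitted, time_ms, peak, avg_latency,
                         halfwidth = wavelet_config()$readoff_halfwidth[[peak]]) {
  lo <- avg_latency - halfwidth
  hi <- avg_latency + halfwidth
  if (lo < min(time_ms) || hi > max(time_ms))
    stop("read-off window [", lo, ", ", hi, "] ms lies outside the epoch",
         call. = FALSE)
  win <- which(time_ms >= lo & time_ms <= hi)
  pol <- if (grepl("^N", peak)) -1 else 1
  v <- pol * fitted[win]
  if (!any(v > 0))
    return(list(present = 0L, amplitude = NA_real_, latency = NA_real_))
  i <- win[which.max(v)]
  list(present = 1L, amplitude = fitted[i], latency = time_ms[i])
}

#' @noRd
decimate_epochs <- function(e, rate) {
  if (rate >= e$fs) return(e)
  k <- e$fs / rate
  if (abs(k - round(k)) > 1e-9)
    stop("analysis_rate must divide the sampling rate", call. = FALSE)
  k <- as.integer(round(k))
  keep <- seq(1, ncol(e$traces), by = k)
  traces <- t(apply(e$traces, 1, function(x)
    fft_bandpass(x, e$fs, low = 0, high = 0.45 * rate, order = 8L)[keep]))
  structure(list(subject_id = e$subject_id, traces = traces,
                 time_ms = e$time_ms[keep], intensity = e$intensity,
                 fs = rate), class = "epoch_set")
}

#' Run the WVLT detector over a whole study
#'
#' Per subject: decimate the epochs to the analysis rate, compute the
#' across-trial mean Morlet power and threshold it into a binary mask, filter
#' every trial through the mask, build regression passes from the filtered
#' average ERP (peak latencies found automatically within `search_windows`
#' unless supplied), fit every trial, and read off the peaks within windows
#' centred on the average-ERP latencies. N1 is read from the fit of pass A,
#' N2 from pass B, and P2 from pass A (falling back to pass B). A peak whose
#' latency cannot be determined on the filtered average is reported absent in
#' every trial of that subject.
#'
#' @param epochs List of `epoch_set` objects.
#' @param config A [wavelet_config()].
#' @param peak_latencies Optional named vector (`N1`, `N2`, `P2`, in ms) used
#'   for every subject in place of the automatic search (the manual-selection
#'   escape hatch).
#' @param search_windows Per-peak latency search windows (ms) on the filtered
#'   average.
#' @return Named list of per-subject [detection_table()]s with
#'   `attr(, "method") == "WVLT"`.
#' @export
detect_study_wvlt <- function(epochs, config = wavelet_config(),
                              peak_latencies = NULL,
                              search_windows = list(N1 = c(50, 130),
                                                    N2 = c(110, 200),
                                                    P2 = c(180, 400))) {
  tabs <- lapply(epochs, function(e) {
    e <- decimate_epochs(e, config$analysis_rate)
    nt <- nrow(e$traces)
    bank <- morlet_bank(e$fs, ncol(e$traces), config)

    mean_pw <- 0
    for (i in seq_len(nt)) mean_pw <- mean_pw + Mod(bank_cwt(e$traces[i, ], bank))^2
    mean_pw <- mean_pw / nt
    mask <- mean_pw >= config$threshold * max(mean_pw)

    filt <- matrix(0, nrow = nt, ncol = ncol(e$traces))
    for (i in seq_len(nt)) {
      W <- bank_cwt(e$traces[i, ], bank)
      W[!mask] <- 0i
      filt[i, ] <- bank_icwt(W, bank)
    }
    favg <- colMeans(filt)

    lats <- peak_latencies %||% find_avg_latencies(favg, e$time_ms, search_windows)
    # a peak without a distinct extremum on the filtered average (overlapping
    # N1/N2 often merge) still gets a nominal latency, mimicking the manual
    # selection step, provided the average has the right polarity there
    for (pk in names(lats)) {
      if (!is.na(lats[[pk]])) next
      cand <- mean(search_windows[[pk]])
      pol <- if (grepl("^N", pk)) -1 else 1
      if (sign(favg[lat_index(e$time_ms, cand)]) == pol) {
        message("no filtered-average extremum for ", pk, " (subject ",
                e$subject_id, "); using the nominal window center")
        lats[[pk]] <- cand
      }
    }
    passes <- build_regressors(favg, e$time_ms, lats)

    rows <- lapply(seq_len(nt), function(i) {
      fitA <- if (!is.null(passes$A)) fit_trial(filt[i, ], passes$A) else NULL
      fitB <- if (!is.null(passes$B)) fit_trial(filt[i, ], passes$B) else NULL
      read <- function(pk, fit) {
        if (is.null(fit) || is.na(lats[[pk]]))
          return(list(present = 0L, amplitude = NA_real_, latency = NA_real_))
        extract_peak(fit$fitted, e$time_ms, pk, lats[[pk]],
                     config$readoff_halfwidth[[pk]])
      }
      n1 <- read("N1", fitA)
      n2 <- read("N2", fitB)
      p2 <- read("P2", if (!is.null(fitA) && "P2" %in% passes$A$peaks) fitA else fitB)
      detection_table(
        trial = i,
        n1_lat = n1$latency, n2_lat = n2$latency, p2_lat = p2$latency,
        n1_amp = n1$amplitude, n2_amp = n2$amplitude, p2_amp = p2$amplitude,
        n1_pres = n1$present, n2_pres = n2$present, p2_pres = p2$present,
        intensity = e$intensity[i])
    })
    out <- do.call(rbind, rows)
    class(out) <- c("detection_table", "data.frame")
    out
  })
  names(tabs) <- vapply(epochs, function(e) as.character(e$subject_id),
                        character(1))
  attr(tabs, "method") <- "WVLT"
  tabs
}

# Automatic stand-in for the manual latency selection on the (filtered)
# average ERP: per peak, the correct-polarity extremum with the largest
# magnitude within the search window; a shared N1/N2 minimum goes to the
# nearer window center. Peaks without an admissible extremum get NA.
#' @noRd
find_avg_latencies <- function(avg, time_ms, search_windows) {
  ext <- local_extrema(avg, time_ms)
  pol <- c(N1 = -1, N2 = -1, P2 = 1)
  pick <- function(pk, exclude = integer(0)) {
    cand <- if (pol[[pk]] < 0) ext$minima else ext$maxima
    win <- search_windows[[pk]]
    cand <- cand[cand$latency >= win[1] & cand$latency <= win[2] &
                 sign(cand$amplitude) == pol[[pk]] &
                 !(cand$index %in% exclude), , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand[which.max(abs(cand$amplitude)), ]
  }
  sel <- list(N1 = pick("N1"), N2 = pick("N2"), P2 = pick("P2"))
  if (!is.null(sel$N1) && !is.null(sel$N2) && sel$N1$index == sel$N2$index) {
    mid <- vapply(search_windows[c("N1", "N2")], mean, numeric(1))
    keep <- if (abs(sel$N1$latency - mid[["N1"]]) <=
                abs(sel$N2$latency - mid[["N2"]])) "N1" else "N2"
    other <- setdiff(c("N1", "N2"), keep)
    sel[[other]] <- pick(other, exclude = sel[[keep]]$index)
  }
  vapply(c("N1", "N2", "P2"), function(pk)
    if (is.null(sel[[pk]])) NA_real_ else sel[[pk]]$latency, numeric(1))
}
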