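#' Construct a per-subject detection table
#'
#' A detection table holds, for each trial of one subject, the N1/N2/P2
#' latencies (ms), amplitudes (microvolts), presence flags (0/1) and the
#' stimulation intensity code -- the same ten quantities, in the same order, as
#' the columns of the study's per-subject result arrays. When a peak is marked
#' absent its amplitude and latency are stored as `NA` regardless of input.
#'
#' @param trial Trial indices.
#' @param n1_lat,n2_lat,p2_lat Latencies in ms.
#' @param n1_amp,n2_amp,p2_amp Amplitudes in microvolts.
#' @param n1_pres,n2_pres,p2_pres Presence flags (0/1).
#' @param intensity Intensity codes (integers 1..6 by convention).
#' @return A validated `data.frame` of class `detection_table`.
#' @export
detection_table <- function(trial, n1_lat, n2_lat, p2_lat,
                            n1_amp, n2_amp, p2_amp,
                            n1_pres, n2_pres, p2_pres, intensity) {
  d <- data.frame(trial = as.integer(trial),
                  n1_lat = as.numeric(n1_lat), n2_lat = as.numeric(n2_lat),
                  p2_lat = as.numeric(p2_lat),
                  n1_amp = as.numeric(n1_amp), n2_amp = as.numeric(n2_amp),
                  p2_amp = as.numeric(p2_amp),
                  n1_pres = as.integer(n1_pres), n2_pres = as.integer(n2_pres),
                  p2_pres = as.integer(p2_pres),
                  intensity = as.integer(intensity))
  validate_detection_table(d)
  for (pk in c("n1", "n2", "p2")) {
    absent <- d[[paste0(pk, "_pres")]] == 0L
    d[[paste0(pk, "_amp")]][absent] <- NA_real_
    d[[paste0(pk, "_lat")]][absent] <- NA_real_
  }
  class(d) <- c("detection_table", "data.frame")
  d
}

#' @noRd
validate_detection_table <- function(d, subject = NULL) {
  who <- if (is.null(subject)) "" else paste0(" (subject ", subject, ")")
  for (pk in c("n1", "n2", "p2")) {
    p <- d[[paste0(pk, "_pres")]]
    bad <- which(!p %in% c(0L, 1L))
    if (length(bad))
      stop("presence flags must be 0 or 1", who, "; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(d$intensity) | d$intensity < 1)
  if (length(bad))
    stop("intensity codes must be positive integers", who,
         "; offending row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  invisible(d)
}

s1_long_cols <- c("method", "subject", "trial", "peak", "present",
                  "amplitude_uV", "latency_ms", "intensity_code")

#' Write a detection-table set to the long-format CSV container
#'
#' The container is a tidy long-format CSV with columns `method, subject,
#' trial, peak, present, amplitude_uV, latency_ms, intensity_code`, one row per
#' trial x peak. Numeric values are written with round-trip precision so that
#' [read_detection_container()] restores them exactly; absent peaks are stored
#' with `NA` amplitude/latency.
#'
#' @param tables Named list of [detection_table()] objects (names are subject
#'   ids), typically with a `method` attribute.
#' @param path Output file path.
#' @param method Method label; defaults to `attr(tables, "method")`.
#' @return The path, invisibly.
#' @export
write_detection_container <- function(tables, path,
                                      method = attr(tables, "method") %||% "UNKNOWN") {
  rows <- lapply(names(tables) %||% as.character(seq_along(tables)), function(sid) {
    d <- tables[[sid]]
    validate_detection_table(d, sid)
    do.call(rbind, lapply(c("N1", "N2", "P2"), function(pk) {
      lp <- tolower(pk)
      data.frame(method = method, subject = sid, trial = d$trial, peak = pk,
                 present = d[[paste0(lp, "_pres")]],
                 amplitude_uV = d[[paste0(lp, "_amp")]],
                 latency_ms = d[[paste0(lp, "_lat")]],
                 intensity_code = d$intensity, stringsAsFactors = FALSE)
    }))
  })
  long <- do.call(rbind, rows)
  if (is.null(long))
    long <- as.data.frame(stats::setNames(rep(list(logical(0)), length(s1_long_cols)),
                                          s1_long_cols))
  long <- long[order(long$subject, long$trial, match(long$peak, c("N1", "N2", "P2"))), ]
  write_csv_exact(long, path)
}

#' Read a long-format CSV detection container
#'
#' Validates the container layout (column set, presence flags in \{0, 1\},
#' positive intensity codes) and returns one detection table per subject.
#' Whatever values occupy the amplitude/latency fields of absent peaks are
#' discarded and treated as missing.
#'
#' @param path Path to a CSV written by [write_detection_container()] (or any
#'   file following the same layout).
#' @return Named list of [detection_table()] objects with a `method` attribute.
#' @export
read_detection_container <- function(path) {
  if (!file.exists(path)) stop("no such container: ", path, call. = FALSE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(long)), sort(s1_long_cols)))
    stop("malformed container ", path, ": expected ", length(s1_long_cols),
         " columns (", paste(s1_long_cols, collapse = ", "), "), got ",
         ncol(long), " (", paste(names(long), collapse = ", "), ")",
         call. = FALSE)
  if (nrow(long) == 0) {
    out <- list()
    attr(out, "method") <- NA_character_
    return(out)
  }
  bad <- which(!long$present %in% c(0, 1))
  if (length(bad))
    stop("presence values outside {0,1} in ", path, "; subject ",
         long$subject[bad[1]], ", row ", bad[1], call. = FALSE)
  subjects <- unique(long$subject)
  out <- lapply(subjects, function(sid) {
    ls <- long[long$subject == sid, ]
    wide <- lapply(c("N1", "N2", "P2"), function(pk) {
      w <- ls[ls$peak == pk, c("trial", "present", "amplitude_uV", "latency_ms",
                               "intensity_code")]
      w[order(w$trial), ]
    })
    names(wide) <- c("N1", "N2", "P2")
    if (!all(wide$N1$trial == wide$N2$trial) ||
        !all(wide$N1$trial == wide$P2$trial))
      stop("inconsistent trial sets across peaks for subject ", sid,
           " in ", path, call. = FALSE)
    detection_table(
      trial = wide$N1$trial,
      n1_lat = wide$N1$latency_ms, n2_lat = wide$N2$latency_ms,
      p2_lat = wide$P2$latency_ms,
      n1_amp = wide$N1$amplitude_uV, n2_amp = wide$N2$amplitude_uV,
      p2_amp = wide$P2$amplitude_uV,
      n1_pres = wide$N1$present, n2_pres = wide$N2$present,
      p2_pres = wide$P2$present,
      intensity = wide$N1$intensity_code)
  })
  names(out) <- as.character(subjects)
  attr(out, "method") <- long$method[1]
  out
}

#' Band-pass filter and baseline-correct epochs
#'
#' Applies an exactly zero-phase band-pass (squared Butterworth magnitude
#' response, applied in the frequency domain) to each epoch and subtracts the
#' mean of the pre-stimulus interval, so latency estimates are not phase
#' shifted and the pre-stimulus mean is zero to numerical precision.
#'
#' @param traces Numeric matrix (trials x samples) or a single numeric vector.
#' @param time_ms Time axis in ms (stimulus onset at 0).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (`low < high < fs/2`).
#' @param pre_stimulus Interval `c(from, to)` in ms used for baseline
#'   correction; must lie inside the epoch window.
#' @param order Butterworth order of each (high-/low-pass) branch.
#' @return Filtered, baseline-corrected matrix of the same shape as `traces`.
#' @export
bandpass_epoch_baseline <- function(traces, time_ms, fs, low = 0.5, high = 30,
                                    pre_stimulus = c(min(time_ms), 0),
                                    order = 4L) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  if (ncol(traces) != length(time_ms))
    stop("traces and time_ms do not match", call. = FALSE)
  if (!(low < high && high < fs / 2))
    stop("need low < high < Nyquist", call. = FALSE)
  if (pre_stimulus[1] < min(time_ms) - 1e-9 ||
      pre_stimulus[2] > max(time_ms) + 1e-9)
    stop("pre_stimulus interval lies outside the epoch window", call. = FALSE)
  base_idx <- which(time_ms >= pre_stimulus[1] & time_ms <= pre_stimulus[2])
  if (length(base_idx) == 0)
    stop("pre_stimulus interval contains no samples", call. = FALSE)
  out <- traces
  for (i in seq_len(nrow(traces))) {
    y <- fft_bandpass(traces[i, ], fs, low, high, order)
    out[i, ] <- y - mean(y[base_idx])
  }
  out
}

#' Export an epoch set (or list of epoch sets) as long-format CSV
#'
#' Columns: `subject, trial, time_ms, voltage_uV, intensity_code`.
#'
#' @param epochs An `epoch_set` or list of them (from [simulate_study()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  rows <- lapply(epochs, function(e) {
    nt <- nrow(e$traces)
    data.frame(subject = e$subject_id,
               trial = rep(seq_len(nt), each = length(e$time_ms)),
               time_ms = rep(e$time_ms, nt),
               voltage_uV = as.vector(t(e$traces)),
               intensity_code = rep(e$intensity, each = length(e$time_ms)))
  })
  write_csv_exact(do.call(rbind, rows), path)
}
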