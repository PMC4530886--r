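#' Simulation configuration for synthetic single-trial ERP studies
#'
#' Builds and validates the configuration object used by [simulate_trial()] and
#' [simulate_study()]. The defaults emulate a graded electrical-stimulation
#' experiment recorded from a single vertex-like channel: 2000 ms epochs
#' (200 ms pre-stimulus) sampled at 2048 Hz, sixteen subjects, six stimulation
#' intensities expressed as multiples of the reflex threshold (0.50 to 2.00),
#' and three peaks -- N1 (~90 ms, negative), N2 (~140 ms, negative) and
#' P2 (~250 ms, positive) -- whose amplitude grows linearly and whose presence
#' probability grows logistically with intensity.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Epoch limits in ms relative to stimulus onset,
#'   `c(pre, post)` with `pre < 0 < post`. Samples lie on a half-open grid
#'   starting at `pre`.
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_intensity Trials per stimulation intensity per subject.
#' @param intensity_ratios Stimulation intensities as multiples of the reflex
#'   threshold, strictly increasing; intensity codes are `seq_along()` of this.
#' @param peak_templates Data frame with one row per peak and columns
#'   `peak`, `polarity` (-1/+1), `lat_mean`, `lat_sd` (ms), `amp_base`
#'   (microvolt magnitude at 1.00 x RTh), `amp_slope` (microvolt per unit
#'   intensity ratio), `amp_sd`, `half_width` (half-width at half-maximum of
#'   the Gaussian bump, ms),
#'   `pres_mid`, `pres_scale` (logistic presence model on the intensity-ratio
#'   axis: `plogis((ratio - pres_mid) / pres_scale)`).
#' @param noise_sd Background noise standard deviation in microvolts
#'   (0 disables noise).
#' @param noise_ar Lag-1 autocorrelation of the coloured noise component; the
#'   background is a mixture of an AR(1) process and white noise approximating
#'   band-limited EEG.
#' @param noise_ar_frac Fraction of the noise variance carried by the AR(1)
#'   component (the remainder is white).
#' @param amp_floor Minimum peak magnitude in microvolts after amplitude
#'   jitter (drawn magnitudes are truncated from below so present peaks are
#'   never degenerate).
#' @param rejection_rate Probability that a trial is discarded, mimicking
#'   artifact pruning; 0 by default.
#' @param seed Integer seed; one seed fans out to per-subject substreams so
#'   whole studies and individual subjects are reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 2048,
                       epoch_window = c(-200, 1800),
                       n_subjects = 16,
                       n_trials_per_intensity = 20,
                       intensity_ratios = c(0.50, 0.75, 1.00, 1.25, 1.50, 2.00),
                       peak_templates = default_peak_templates(),
                       noise_sd = 10,
                       noise_ar = 0.976,
                       noise_ar_frac = 0.9,
                       amp_floor = 0.5,
                       rejection_rate = 0,
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, epoch_window = epoch_window,
              n_subjects = as.integer(n_subjects),
              n_trials_per_intensity = as.integer(n_trials_per_intensity),
              intensity_ratios = intensity_ratios,
              peak_templates = peak_templates,
              noise_sd = noise_sd, noise_ar = noise_ar,
              noise_ar_frac = noise_ar_frac, amp_floor = amp_floor,
              rejection_rate = rejection_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default peak templates (N1/N2/P2)
#'
#' Gaussian-bump templates for the three characteristic peaks. Half-widths
#' (at half-maximum) default to 20/25/60 ms so that adjacent N1 and N2 bumps
#' overlap, as they do in vertex recordings, while remaining resolvable as
#' distinct minima at comparable amplitudes. The logistic presence parameters
#' yield average presence rates of roughly 0.8 (N1), 0.6 (N2) and 0.95 (P2)
#' across the six default intensities.
#'
#' @return A data frame with one row per peak.
#' @export
default_peak_templates <- function() {
  data.frame(
    peak = c("N1", "N2", "P2"),
    polarity = c(-1, -1, 1),
    lat_mean = c(90, 140, 250),
    lat_sd = c(10, 10, 15),
    amp_base = c(15, 15, 20),
    amp_slope = c(8, 8, 10),
    amp_sd = c(3, 3, 4),
    half_width = c(20, 25, 60),
    pres_mid = c(0.60, 0.95, 0.30),
    pres_scale = c(0.20, 0.30, 0.15),
    stringsAsFactors = FALSE
  )
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$epoch_window[1] < 0 && cfg$epoch_window[2] > 0))
    stop("epoch_window must span stimulus onset (0 ms)", call. = FALSE)
  if (any(diff(cfg$intensity_ratios) <= 0))
    stop("intensity_ratios must be strictly increasing", call. = FALSE)
  pt <- cfg$peak_templates
  req <- c("peak", "polarity", "lat_mean", "lat_sd", "amp_base", "amp_slope",
           "amp_sd", "half_width", "pres_mid", "pres_scale")
  if (!all(req %in% names(pt)))
    stop("peak_templates is missing columns: ",
         paste(setdiff(req, names(pt)), collapse = ", "), call. = FALSE)
  if (any(pt$lat_sd < 0) || any(pt$amp_sd < 0) || cfg$noise_sd < 0)
    stop("all standard deviations must be >= 0", call. = FALSE)
  if (!all(pt$polarity %in% c(-1, 1)))
    stop("peak polarity must be -1 or +1", call. = FALSE)
  probs <- stats::plogis(outer(cfg$intensity_ratios, pt$pres_mid, "-") /
                         rep(pt$pres_scale, each = length(cfg$intensity_ratios)))
  if (any(probs < 0 | probs > 1))
    stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$rejection_rate < 0 || cfg$rejection_rate >= 1)
    stop("rejection_rate must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Presence probability of each peak at a given intensity
#'
#' @param config A [sim_config()] object.
#' @param intensity_code Integer code into `config$intensity_ratios`.
#' @return Named numeric vector of probabilities, one per peak.
#' @export
presence_probability <- function(config, intensity_code) {
  ratio <- intensity_ratio(config, intensity_code)
  pt <- config$peak_templates
  stats::setNames(stats::plogis((ratio - pt$pres_mid) / pt$pres_scale), pt$peak)
}

#' @noRd
intensity_ratio <- function(config, intensity_code) {
  code <- as.integer(intensity_code)
  if (is.na(code) || code < 1 || code > length(config$intensity_ratios))
    stop("unknown intensity_code: ", intensity_code, call. = FALSE)
  config$intensity_ratios[code]
}

# Background noise: AR(1) (initialised at its stationary distribution) plus
# white noise, mixed so the total SD equals noise_sd.
#' @noRd
simulate_noise <- function(n, cfg) {
  if (cfg$noise_sd == 0) return(numeric(n))
  sd_ar <- cfg$noise_sd * sqrt(cfg$noise_ar_frac)
  sd_wh <- cfg$noise_sd * sqrt(1 - cfg$noise_ar_frac)
  ar <- numeric(n)
  if (sd_ar > 0) {
    innov_sd <- sd_ar * sqrt(1 - cfg$noise_ar^2)
    ar <- as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd),
                                   cfg$noise_ar, method = "recursive",
                                   init = stats::rnorm(1, sd = sd_ar)))
  }
  ar + stats::rnorm(n, sd = sd_wh)
}

#' Simulate one single-trial ERP epoch
#'
#' Draws peak presence, latency and amplitude from the configured templates,
#' renders each present peak as a Gaussian bump of the configured polarity and
#' half-width, and adds background noise. Ground truth records both the drawn
#' template parameters and the *realized* extremum of the clean (noise-free)
#' trace nearest to the drawn latency; overlapping bumps shift each other's
#' extrema, and the realized values are what detectors can actually recover.
#'
#' @param config A [sim_config()] object.
#' @param intensity_code Intensity code (index into `config$intensity_ratios`).
#' @return A list with `trace` (voltage in microvolts), `time_ms`, and `truth`
#'   (one-row data frame with `<peak>_present`, `<peak>_amp`, `<peak>_lat`
#'   columns; absent peaks carry `NA` amplitude/latency).
#' @export
simulate_trial <- function(config, intensity_code) {
  validate_sim_config(config)
  ratio <- intensity_ratio(config, intensity_code)
  t_ms <- time_axis(config$epoch_window, config$sampling_rate)
  pt <- config$peak_templates
  n_pk <- nrow(pt)

  sigma <- pt$half_width / sqrt(2 * log(2)) # half-width at half-maximum -> SD
  present <- stats::runif(n_pk) < stats::plogis((ratio - pt$pres_mid) / pt$pres_scale)
  lat <- stats::rnorm(n_pk, pt$lat_mean, pt$lat_sd)
  # keep drawn latencies well inside the epoch
  lat <- pmin(pmax(lat, config$epoch_window[1] + 4 * sigma),
              config$epoch_window[2] - 4 * sigma)
  amp <- pmax(config$amp_floor,
              stats::rnorm(n_pk, pt$amp_base + pt$amp_slope * (ratio - 1), pt$amp_sd))

  clean <- numeric(length(t_ms))
  for (k in seq_len(n_pk)) {
    if (present[k]) {
      clean <- clean + pt$polarity[k] * amp[k] *
        exp(-(t_ms - lat[k])^2 / (2 * sigma[k]^2))
    }
  }
  trace <- clean + simulate_noise(length(t_ms), config)

  truth <- realize_truth(clean, t_ms, pt, present, amp, lat)
  truth$intensity <- as.integer(intensity_code)
  list(trace = trace, time_ms = t_ms, truth = truth)
}

# Measure the realized extremum of the clean trace for each present peak:
# the correct-polarity local extremum nearest the drawn latency. Falls back to
# the drawn values in the degenerate case of no matching extremum.
#' @noRd
realize_truth <- function(clean, t_ms, pt, present, amp, lat) {
  ext <- local_extrema(clean, t_ms)
  out <- list()
  for (k in seq_len(nrow(pt))) {
    pk <- tolower(pt$peak[k])
    if (!present[k]) {
      out[[paste0(pk, "_present")]] <- 0L
      out[[paste0(pk, "_amp")]] <- NA_real_
      out[[paste0(pk, "_lat")]] <- NA_real_
      next
    }
    cand <- if (pt$polarity[k] < 0) ext$minima else ext$maxima
    cand <- cand[sign(cand$amplitude) == pt$polarity[k], , drop = FALSE]
    if (nrow(cand) == 0) {
      r_amp <- pt$polarity[k] * amp[k]
      r_lat <- lat[k]
    } else {
      i <- which.min(abs(cand$latency - lat[k]))
      r_amp <- cand$amplitude[i]
      r_lat <- cand$latency[i]
    }
    out[[paste0(pk, "_present")]] <- 1L
    out[[paste0(pk, "_amp")]] <- r_amp
    out[[paste0(pk, "_lat")]] <- r_lat
  }
  as.data.frame(out)
}

#' Simulate a full multi-subject study
#'
#' Generates `n_subjects` epoch sets with the per-intensity trial counts of the
#' configuration (by default 6 intensities x 20 trials = 120 trials per
#' subject). The top-level seed fans out to one substream per subject, so the
#' whole study and any individual subject are reproducible.
#'
#' @param config A [sim_config()] object.
#' @return A list with `epochs` (list of `epoch_set` objects: `subject_id`,
#'   `traces` trials x samples matrix, `time_ms`, `intensity`, `fs`) and
#'   `truth` (data frame over all subjects and trials).
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  n_int <- length(config$intensity_ratios)
  epochs <- vector("list", config$n_subjects)
  truth_all <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    set.seed(sub_seeds[s])
    codes <- rep(seq_len(n_int), each = config$n_trials_per_intensity)
    if (config$rejection_rate > 0) {
      keep <- stats::runif(length(codes)) >= config$rejection_rate
      codes <- codes[keep]
    }
    t_ms <- time_axis(config$epoch_window, config$sampling_rate)
    traces <- matrix(0, nrow = length(codes), ncol = length(t_ms))
    truth_s <- vector("list", length(codes))
    for (i in seq_along(codes)) {
      tr <- simulate_trial(config, codes[i])
      traces[i, ] <- tr$trace
      truth_s[[i]] <- cbind(data.frame(subject = s, trial = i), tr$truth)
    }
    epochs[[s]] <- structure(
      list(subject_id = s, traces = traces, time_ms = t_ms,
           intensity = as.integer(codes), fs = config$sampling_rate),
      class = "epoch_set")
    truth_all[[s]] <- do.call(rbind, truth_s)
  }
  list(epochs = epochs, truth = do.call(rbind, truth_all))
}

#' Convert simulator ground truth to a detection table set
#'
#' Reshapes the `truth` component of [simulate_study()] into the same
#' per-subject detection-table form produced by the detectors, so the ground
#' truth can enter agreement analyses as a method named `"TRUTH"`.
#'
#' @param truth The `truth` data frame from [simulate_study()].
#' @return A named list of per-subject detection tables (see
#'   [detection_table()]).
#' @export
truth_detection_tables <- function(truth) {
  split_truth <- split(truth, truth$subject)
  tabs <- lapply(split_truth, function(d) {
    detection_table(
      trial = d$trial,
      n1_lat = d$n1_lat, n2_lat = d$n2_lat, p2_lat = d$p2_lat,
      n1_amp = d$n1_amp, n2_amp = d$n2_amp, p2_amp = d$p2_amp,
      n1_pres = d$n1_present, n2_pres = d$n2_present, p2_pres = d$p2_present,
      intensity = d$intensity)
  })
  names(tabs) <- names(split_truth)
  attr(tabs, "method") <- "TRUTH"
  tabs
}
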