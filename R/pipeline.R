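# End-to-end orchestration: simulate -> detect (DRIV, WVLT) -> per-subject
# pairwise agreement -> group statistics -> report bundle; plus the
# reproduction run on a set of previously recorded detection containers.

#' Per-method summary of detected peaks (amplitude, latency, counts)
#'
#' For each method and peak: the per-subject mean amplitude and latency over
#' detected trials and the per-subject number of detected peaks, aggregated
#' as mean and SD across subjects. A pooled-across-trials variant of the
#' amplitude/latency summaries is included for comparison.
#'
#' @param method_tables Named list (method -> named list of per-subject
#'   [detection_table()]s).
#' @return Data frame with columns `method`, `peak`, `quantity`,
#'   `mean`, `sd`, `pooled_mean`, `pooled_sd`.
#' @export
summarize_detections <- function(method_tables) {
  rows <- list()
  for (method in names(method_tables)) {
    tabs <- method_tables[[method]]
    for (pk in c("N1", "N2", "P2")) {
      lp <- tolower(pk)
      per_sub <- lapply(tabs, function(d) {
        pres <- d[[paste0(lp, "_pres")]] == 1L
        c(amp = mean(d[[paste0(lp, "_amp")]][pres]),
          lat = mean(d[[paste0(lp, "_lat")]][pres]),
          count = sum(pres))
      })
      ps <- do.call(rbind, per_sub)
      pooled_amp <- unlist(lapply(tabs, function(d)
        d[[paste0(lp, "_amp")]][d[[paste0(lp, "_pres")]] == 1L]))
      pooled_lat <- unlist(lapply(tabs, function(d)
        d[[paste0(lp, "_lat")]][d[[paste0(lp, "_pres")]] == 1L]))
      pooled <- list(amplitude_uV = pooled_amp, latency_ms = pooled_lat,
                     n_detected = NULL)
      for (q in c("amplitude_uV", "latency_ms", "n_detected")) {
        col <- c(amplitude_uV = "amp", latency_ms = "lat", n_detected = "count")[[q]]
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, peak = pk, quantity = q,
          mean = mean(ps[, col], na.rm = TRUE),
          sd = stats::sd(ps[, col], na.rm = TRUE),
          pooled_mean = if (is.null(pooled[[q]])) NA_real_ else mean(pooled[[q]]),
          pooled_sd = if (is.null(pooled[[q]])) NA_real_ else stats::sd(pooled[[q]]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-subject agreement indices for every pairing of methods
#'
#' @param method_tables Named list (method -> named list of per-subject
#'   [detection_table()]s); all methods must cover the same subjects.
#' @param pairings Optional list of 2-element character vectors; defaults to
#'   all unordered method pairs.
#' @return Long data frame: `pairing`, `subject`, `peak`, `feature`, `index`,
#'   `value`, `n_pairs`.
#' @export
pairing_agreement <- function(method_tables, pairings = NULL) {
  methods <- names(method_tables)
  if (is.null(pairings)) {
    pairings <- utils::combn(methods, 2, simplify = FALSE)
  }
  subjects <- names(method_tables[[1]])
  rows <- list()
  for (pr in pairings) {
    ta <- method_tables[[pr[1]]]
    tb <- method_tables[[pr[2]]]
    for (s in subjects) {
      ai <- agreement_indices(ta[[s]], tb[[s]])
      ai <- cbind(data.frame(pairing = paste(pr, collapse = "-"), subject = s),
                  ai)
      rows[[length(rows) + 1L]] <- ai
    }
  }
  do.call(rbind, rows)
}

# Subjects x pairings matrix of one index, from the long agreement table.
#' @noRd
index_matrix <- function(agree_long, peak, feature, index) {
  sel <- agree_long[agree_long$peak == peak & agree_long$feature == feature &
                    agree_long$index == index, ]
  pairings <- unique(sel$pairing)
  subjects <- unique(sel$subject)
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(pairings),
              dimnames = list(subjects, pairings))
  for (i in seq_len(nrow(sel))) m[sel$subject[i], sel$pairing[i]] <- sel$value[i]
  m
}

#' Friedman tests across pairings for every peak and index
#'
#' @param agree_long Output of [pairing_agreement()].
#' @param indices Which (feature, index) combinations to test.
#' @return Data frame: `peak`, `feature`, `index`, `chi2`, `df`, `p`, `n`.
#' @export
friedman_across_pairings <- function(agree_long,
                                     indices = list(
                                       c("presence", "p_o"),
                                       c("presence", "p_pos"),
                                       c("presence", "p_neg"),
                                       c("presence", "p_e"),
                                       c("presence", "kappa"),
                                       c("amplitude", "bias"),
                                       c("amplitude", "loa"),
                                       c("amplitude", "icc"),
                                       c("amplitude", "cv"),
                                       c("latency", "bias"),
                                       c("latency", "loa"),
                                       c("latency", "icc"),
                                       c("latency", "cv"))) {
  rows <- list()
  for (pk in c("N1", "N2", "P2")) {
    for (ix in indices) {
      m <- index_matrix(agree_long, pk, ix[1], ix[2])
      fr <- tryCatch(suppressWarnings(friedman_ranks(m)), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        peak = pk, feature = ix[1], index = ix[2],
        chi2 = if (is.null(fr)) NA_real_ else fr$chi2,
        df = if (is.null(fr)) NA_real_ else fr$df,
        p = if (is.null(fr)) NA_real_ else fr$p,
        n = if (is.null(fr)) NA_integer_ else fr$n)
    }
  }
  do.call(rbind, rows)
}

#' Run a full simulated agreement study
#'
#' Simulates a study, band-pass filters and baseline-corrects the epochs, runs
#' both automated detectors, assembles per-subject detection tables for the
#' ground truth and the two detectors, computes per-subject agreement indices
#' for every pairing, Friedman tests across pairings, and intensity-stratified
#' kappa/CV for the detector pairing. When `out_dir` is given the bundle is
#' written out as CSV tables plus a JSON summary; outputs carry the seed and a
#' configuration fingerprint and are byte-identical across re-runs with the
#' same configuration.
#'
#' @param config A [sim_config()].
#' @param wconfig A [wavelet_config()].
#' @param out_dir Optional output directory.
#' @param bandpass Band edges in Hz for epoch preprocessing (`NULL` skips).
#' @return Invisible list with `detections`, `agreement`, `friedman`,
#'   `intensity_kappa`, `intensity_cv`, `summary`.
#' @export
run_simulated_study <- function(config = sim_config(),
                                wconfig = wavelet_config(),
                                out_dir = NULL,
                                bandpass = c(0.5, 30)) {
  sim <- simulate_study(config)
  epochs <- sim$epochs
  if (!is.null(bandpass)) {
    epochs <- lapply(epochs, function(e) {
      e$traces <- bandpass_epoch_baseline(e$traces, e$time_ms, e$fs,
                                          bandpass[1], bandpass[2])
      e
    })
  }
  detections <- list(TRUTH = truth_detection_tables(sim$truth),
                     DRIV = detect_study_driv(epochs),
                     WVLT = detect_study_wvlt(epochs, wconfig))

  agree <- pairing_agreement(detections)
  fried <- friedman_across_pairings(agree)

  ik <- lapply(stats::setNames(c("N1", "N2", "P2"), c("N1", "N2", "P2")),
               function(pk) stratify_by_intensity(detections$DRIV,
                                                  detections$WVLT, pk, "kappa"))
  icv <- lapply(stats::setNames(c("N1", "N2", "P2"), c("N1", "N2", "P2")),
                function(pk) stratify_by_intensity(detections$DRIV,
                                                   detections$WVLT, pk, "cv",
                                                   feature = "amplitude"))

  cfg_hash <- fnv1a_hash(paste(deparse(config[setdiff(names(config), "seed")]),
                               collapse = ""))
  summ <- list(seed = config$seed, config_hash = cfg_hash,
               n_subjects = config$n_subjects,
               n_trials = sum(vapply(epochs, function(e) nrow(e$traces),
                                     numeric(1))),
               detection_summary = summarize_detections(detections),
               median_kappa = stats::aggregate(
                 value ~ pairing + peak,
                 data = agree[agree$index == "kappa", ],
                 FUN = stats::median, na.action = stats::na.omit))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mth in names(detections))
      write_detection_container(detections[[mth]],
                                file.path(out_dir, paste0("detections_",
                                                          mth, ".csv")), mth)
    write_csv_exact(agree, file.path(out_dir, "agreement_indices.csv"))
    write_csv_exact(fried, file.path(out_dir, "friedman_pairings.csv"))
    write_csv_exact(summ$detection_summary,
                    file.path(out_dir, "detection_summary.csv"))
    jsonlite::write_json(
      list(seed = summ$seed, config_hash = summ$config_hash,
           n_subjects = summ$n_subjects, n_trials = summ$n_trials,
           median_kappa = summ$median_kappa),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(detections = detections, agreement = agree, friedman = fried,
                 intensity_kappa = ik, intensity_cv = icv, summary = summ))
}

#' Reproduction run on recorded detection containers
#'
#' Reads one detection container per method (see
#' [read_detection_container()]), and reproduces the full analysis on them:
#' total analyzed trials, per-method peak summaries, per-subject agreement
#' indices for all method pairings, Friedman tests across pairings for every
#' index and peak, and intensity-stratified kappa (presence) and CV
#' (amplitude and latency) for the best- and worst-performing pairings
#' (observer-observer and detector-detector by convention).
#'
#' @param paths Named character vector of container paths, e.g.
#'   `c(OBS1 = ..., OBS2 = ..., DRIV = ..., WVLT = ...)`.
#' @param out_dir Optional output directory for CSV tables.
#' @param strat_pairings List of 2-element method vectors to stratify by
#'   intensity; defaults to `OBS1-OBS2` and `DRIV-WVLT` when present.
#' @return List with `n_trials_total`, `detection_summary`, `agreement`,
#'   `friedman`, `intensity_kappa`, `intensity_cv`.
#' @export
run_s1_reproduction <- function(paths, out_dir = NULL, strat_pairings = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing detection container(s): ",
         paste(names(missing), unname(missing), sep = " = ", collapse = "; "),
         call. = FALSE)
  detections <- lapply(paths, read_detection_container)
  names(detections) <- names(paths)

  n_trials <- sum(vapply(detections[[1]], nrow, numeric(1)))
  agree <- pairing_agreement(detections)
  fried <- friedman_across_pairings(agree)

  if (is.null(strat_pairings)) {
    strat_pairings <- Filter(function(p) all(p %in% names(detections)),
                             list(c("OBS1", "OBS2"), c("DRIV", "WVLT")))
  }
  strat_k <- list()
  strat_cv <- list()
  for (pr in strat_pairings) {
    key <- paste(pr, collapse = "-")
    strat_k[[key]] <- lapply(
      stats::setNames(c("N1", "N2", "P2"), c("N1", "N2", "P2")),
      function(pk) stratify_by_intensity(detections[[pr[1]]],
                                         detections[[pr[2]]], pk, "kappa"))
    strat_cv[[key]] <- lapply(
      stats::setNames(c("amplitude", "latency"), c("amplitude", "latency")),
      function(ft) lapply(
        stats::setNames(c("N1", "N2", "P2"), c("N1", "N2", "P2")),
        function(pk) stratify_by_intensity(detections[[pr[1]]],
                                           detections[[pr[2]]], pk, "cv",
                                           feature = ft)))
  }

  out <- list(n_trials_total = n_trials,
              detection_summary = summarize_detections(detections),
              agreement = agree, friedman = fried,
              intensity_kappa = strat_k, intensity_cv = strat_cv)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_exact(out$detection_summary,
                    file.path(out_dir, "detection_summary.csv"))
    write_csv_exact(agree, file.path(out_dir, "agreement_indices.csv"))
    write_csv_exact(fried, file.path(out_dir, "friedman_pairings.csv"))
  }
  out
}
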