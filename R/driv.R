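# DRIV: derivative-based single-trial peak detector with quadratic fuzzy-zone
# weighting. Local maxima/minima are located at sign changes of the first
# difference; each candidate is weighted by a per-peak fuzzy zone and the
# admissible candidate (correct amplitude sign, nonzero weight) with the
# largest weighted magnitude is selected.

#' Locate local extrema of a trace
#'
#' Extrema are the points where the first difference changes sign. Plateaus
#' (runs of zero difference flanked by opposite slopes) contribute a single
#' candidate at the run's midpoint sample; endpoints are never returned.
#'
#' @param trace Numeric vector, length >= 3.
#' @param time_ms Optional time axis; defaults to sample indices.
#' @return List with data frames `maxima` and `minima`, each with columns
#'   `index`, `latency`, `amplitude`.
#' @export
local_extrema <- function(trace, time_ms = seq_along(trace)) {
  if (length(trace) < 3) stop("trace must have at least 3 samples", call. = FALSE)
  d <- diff(trace)
  nz <- which(d != 0)
  empty <- data.frame(index = integer(0), latency = numeric(0),
                      amplitude = numeric(0))
  if (length(nz) < 2) return(list(maxima = empty, minima = empty))
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  if (length(chg) == 0) return(list(maxima = empty, minima = empty))
  # slope runs end at sample nz[i] + 1; any plateau extends to nz[i + 1]
  idx <- floor(((nz[chg] + 1L) + nz[chg + 1L]) / 2)
  is_max <- s[chg] > 0
  mk <- function(i) data.frame(index = i, latency = time_ms[i],
                               amplitude = trace[i])
  list(maxima = mk(idx[is_max]), minima = mk(idx[!is_max]))
}

#' Fuzzy zone for one ERP peak
#'
#' A fuzzy zone has a central latency (taken from the average ERP), two
#' boundaries describing the expected latency variability, and a polarity
#' (-1 for N1/N2, +1 for P2). The membership weight is 1 at the center,
#' decreases quadratically towards each boundary, and is 0 outside.
#'
#' @param peak Peak label (`"N1"`, `"N2"` or `"P2"`).
#' @param center Central latency in ms.
#' @param lower,upper Zone boundaries in ms (`lower < center < upper`).
#' @param polarity -1 or +1; defaults to -1 for N peaks, +1 for P peaks.
#' @return A list of class `fuzzy_zone`.
#' @export
fuzzy_zone <- function(peak, center, lower, upper,
                       polarity = if (grepl("^N", peak)) -1 else 1) {
  if (!(lower < center && center < upper))
    stop("need lower < center < upper", call. = FALSE)
  if (!polarity %in% c(-1, 1)) stop("polarity must be -1 or +1", call. = FALSE)
  structure(list(peak = peak, center = center, lower = lower, upper = upper,
                 polarity = polarity), class = "fuzzy_zone")
}

#' Quadratic fuzzy membership weight
#'
#' `w(t) = 1 - ((t - c) / (b - c))^2` with `b` the boundary on `t`'s side of
#' the center `c`; 0 outside the boundaries.
#'
#' @param latency Latency (ms), vectorized.
#' @param zone A [fuzzy_zone()].
#' @return Weights in `[0, 1]`.
#' @export
fuzzy_weight <- function(latency, zone) {
  b <- ifelse(latency < zone$center, zone$lower, zone$upper)
  w <- 1 - ((latency - zone$center) / (b - zone$center))^2
  ifelse(latency <= zone$lower | latency >= zone$upper, 0, pmax(w, 0))
}

#' Build the three fuzzy zones from an average ERP
#'
#' Zone centers are the latencies of the N1/N2/P2 extrema of the average ERP,
#' searched within per-peak latency windows; boundaries are the centers plus or
#' minus the configured half-widths. If the same minimum is the best candidate
#' for both N1 and N2 it is assigned to the nearer nominal window center and
#' the other peak is re-searched among the remaining minima. Supplying
#' `centers` bypasses the search (the manual-centering escape hatch).
#'
#' @param avg_erp Average ERP voltage series.
#' @param time_ms Time axis in ms.
#' @param halfwidths Named vector of boundary half-widths in ms.
#' @param search_windows Named list of `c(from, to)` ms windows in which each
#'   peak's center is searched.
#' @param centers Optional named vector of manual centers (ms); returned
#'   unchanged with the configured boundaries.
#' @param fallback When `TRUE`, a peak without an admissible extremum gets its
#'   center at the midpoint of its search window (with a message) instead of
#'   raising an error -- the automated stand-in for the manual-centering
#'   escape hatch, used by the study driver so that low-signal subjects still
#'   get a zone to search.
#' @return Named list of three [fuzzy_zone()] objects (N1, N2, P2).
#' @export
zones_from_average <- function(avg_erp, time_ms,
                               halfwidths = c(N1 = 35, N2 = 35, P2 = 70),
                               search_windows = list(N1 = c(50, 130),
                                                     N2 = c(110, 200),
                                                     P2 = c(180, 400)),
                               centers = NULL, fallback = FALSE) {
  pol <- c(N1 = -1, N2 = -1, P2 = 1)
  if (!is.null(centers)) {
    zz <- lapply(names(pol), function(pk)
      fuzzy_zone(pk, centers[[pk]], centers[[pk]] - halfwidths[[pk]],
                 centers[[pk]] + halfwidths[[pk]], pol[[pk]]))
    names(zz) <- names(pol)
    return(zz)
  }
  ext <- local_extrema(avg_erp, time_ms)
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
  missing <- names(sel)[vapply(sel, is.null, logical(1))]
  if (length(missing)) {
    if (!fallback)
      stop("no admissible extremum in the average ERP for peak(s) ",
           paste(missing, collapse = ", "),
           "; supply manual centers via `centers`", call. = FALSE)
    message("no average-ERP extremum for ", paste(missing, collapse = ", "),
            "; using nominal search-window centers")
    for (pk in missing)
      sel[[pk]] <- data.frame(latency = mean(search_windows[[pk]]))
  }
  zz <- lapply(names(pol), function(pk)
    fuzzy_zone(pk, sel[[pk]]$latency, sel[[pk]]$latency - halfwidths[[pk]],
               sel[[pk]]$latency + halfwidths[[pk]], pol[[pk]]))
  names(zz) <- names(pol)
  zz
}

# Admissible candidates of a zone, scored by |amplitude| * weight.
#' @noRd
zone_candidates <- function(ext, zone) {
  cand <- if (zone$polarity < 0) ext$minima else ext$maxima
  if (nrow(cand) == 0) return(cand)
  w <- fuzzy_weight(cand$latency, zone)
  ok <- w > 0 & sign(cand$amplitude) == zone$polarity
  cand <- cand[ok, , drop = FALSE]
  cand$weight <- w[ok]
  cand$score <- abs(cand$amplitude) * cand$weight
  cand
}

# Top-scoring candidate; ties broken toward the earlier latency.
#' @noRd
best_candidate <- function(cand, exclude = integer(0)) {
  cand <- cand[!(cand$index %in% exclude), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  top <- cand[cand$score == max(cand$score), , drop = FALSE]
  top[which.min(top$latency), ]
}

#' DRIV single-trial peak detection
#'
#' Finds the local extrema of one trace, weights them within the three fuzzy
#' zones, and selects per zone the admissible candidate (correct amplitude
#' sign, nonzero weight) with the largest weighted magnitude. If the same
#' minimum is the top candidate for both N1 and N2 it is assigned to the zone
#' whose center is nearer, and the other zone is re-searched among the
#' remaining minima; a zone with no admissible candidate yields an absent
#' peak. If the final N1 and N2 latencies come out in reversed order (possible
#' when zones overlap) the two assignments are swapped so that N1 precedes N2.
#'
#' @param trace Voltage series (microvolts).
#' @param time_ms Time axis (ms).
#' @param zones Named list of three [fuzzy_zone()] objects (N1, N2, P2).
#' @param intensity Optional intensity code stored in the output row.
#' @return One-row [detection_table()].
#' @export
detect_peaks_driv <- function(trace, time_ms, zones, intensity = NA_integer_) {
  ext <- local_extrema(trace, time_ms)
  cand <- lapply(zones, function(z) zone_candidates(ext, z))
  pick <- list(N1 = best_candidate(cand$N1),
               N2 = best_candidate(cand$N2),
               P2 = best_candidate(cand$P2))

  if (!is.null(pick$N1) && !is.null(pick$N2) &&
      pick$N1$index == pick$N2$index) {
    lat <- pick$N1$latency
    keep <- if (abs(lat - zones$N1$center) <= abs(lat - zones$N2$center))
      "N1" else "N2"
    other <- setdiff(c("N1", "N2"), keep)
    pick[[other]] <- best_candidate(cand[[other]], exclude = pick[[keep]]$index)
  }
  if (!is.null(pick$N1) && !is.null(pick$N2) &&
      pick$N1$latency > pick$N2$latency) {
    tmp <- pick$N1; pick$N1 <- pick$N2; pick$N2 <- tmp
  }

  val <- function(p, what) if (is.null(p)) NA_real_ else p[[what]]
  detection_table(
    trial = 1L,
    n1_lat = val(pick$N1, "latency"), n2_lat = val(pick$N2, "latency"),
    p2_lat = val(pick$P2, "latency"),
    n1_amp = val(pick$N1, "amplitude"), n2_amp = val(pick$N2, "amplitude"),
    p2_amp = val(pick$P2, "amplitude"),
    n1_pres = as.integer(!is.null(pick$N1)),
    n2_pres = as.integer(!is.null(pick$N2)),
    p2_pres = as.integer(!is.null(pick$P2)),
    intensity = if (is.na(intensity)) 1L else intensity)
}

#' Run the DRIV detector over a whole study
#'
#' For each subject the fuzzy-zone centers are taken from that subject's
#' average ERP (see [zones_from_average()]), then every trial is scored with
#' [detect_peaks_driv()].
#'
#' @param epochs List of `epoch_set` objects (see [simulate_study()]).
#' @param halfwidths,search_windows,centers Passed to [zones_from_average()].
#' @return Named list of per-subject [detection_table()]s with
#'   `attr(, "method") == "DRIV"`.
#' @export
detect_study_driv <- function(epochs,
                              halfwidths = c(N1 = 35, N2 = 35, P2 = 70),
                              search_windows = list(N1 = c(50, 130),
                                                    N2 = c(110, 200),
                                                    P2 = c(180, 400)),
                              centers = NULL) {
  tabs <- lapply(epochs, function(e) {
    avg <- colMeans(e$traces)
    zz <- zones_from_average(avg, e$time_ms, halfwidths, search_windows,
                             centers, fallback = TRUE)
    rows <- lapply(seq_len(nrow(e$traces)), function(i) {
      r <- detect_peaks_driv(e$traces[i, ], e$time_ms, zz, e$intensity[i])
      r$trial <- i
      r
    })
    out <- do.call(rbind, rows)
    class(out) <- c("detection_table", "data.frame")
    out
  })
  names(tabs) <- vapply(epochs, function(e) as.character(e$subject_id),
                        character(1))
  attr(tabs, "method") <- "DRIV"
  tabs
}
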