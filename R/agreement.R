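# Categorical and quantitative agreement between two detection methods.
# Percentages are on the 0-100 scale throughout, matching how the indices are
# conventionally reported.

#' 2x2 contingency table of presence flags
#'
#' @param presence_a,presence_b Equal-length 0/1 vectors (method A, method B).
#' @return List of class `contingency2x2` with counts `a` (both present),
#'   `b` (A only), `c` (B only), `d` (both absent) and `n`.
#' @export
contingency <- function(presence_a, presence_b) {
  stopifnot(length(presence_a) == length(presence_b), length(presence_a) >= 1,
            all(presence_a %in% 0:1), all(presence_b %in% 0:1))
  a <- sum(presence_a == 1 & presence_b == 1)
  b <- sum(presence_a == 1 & presence_b == 0)
  cc <- sum(presence_a == 0 & presence_b == 1)
  d <- sum(presence_a == 0 & presence_b == 0)
  structure(list(a = a, b = b, c = cc, d = d, n = a + b + cc + d),
            class = "contingency2x2")
}

#' Categorical agreement indices from a 2x2 table
#'
#' Computes overall percent agreement `p_o = 100 (a + d) / n`, positive and
#' negative specific agreement `p_pos = 100 * 2a / (2a + b + c)` and
#' `p_neg = 100 * 2d / (2d + b + c)`, chance agreement
#' `p_e = 100 [(a + b)(a + c) + (c + d)(b + d)] / n^2`, and Cohen's kappa
#' `(p_o - p_e) / (100 - p_e)` floored at zero. `p_pos`/`p_neg` are `NA` when
#' their denominator vanishes (no positive, respectively negative, call by
#' either method); kappa is `NA` when `p_e = 100` (degenerate marginals).
#'
#' @param t A [contingency()] table.
#' @return List of class `categorical_agreement` with `p_o`, `p_pos`,
#'   `p_neg`, `p_e`, `kappa` and `kappa_raw` (before flooring).
#' @export
categorical_agreement <- function(t) {
  stopifnot(inherits(t, "contingency2x2"), t$n >= 1)
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d; n <- t$n
  p_o <- 100 * (a + d) / n
  p_pos <- if (2 * a + b + cc == 0) NA_real_ else 100 * 2 * a / (2 * a + b + cc)
  p_neg <- if (2 * d + b + cc == 0) NA_real_ else 100 * 2 * d / (2 * d + b + cc)
  p_e <- 100 * ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  kappa_raw <- if (p_e >= 100 - 1e-12) NA_real_ else (p_o - p_e) / (100 - p_e)
  structure(list(p_o = p_o, p_pos = p_pos, p_neg = p_neg, p_e = p_e,
                 kappa = if (is.na(kappa_raw)) NA_real_ else max(0, kappa_raw),
                 kappa_raw = kappa_raw),
            class = "categorical_agreement")
}

#' Paired feature values over trials where both methods detect the peak
#'
#' Differences between two methods' estimates are only defined on trials in
#' which both report the peak present; this selects those trials, aligned by
#' trial order.
#'
#' @param table_a,table_b [detection_table()]s of the same subject with the
#'   same trial ordering.
#' @param peak `"N1"`, `"N2"` or `"P2"`.
#' @param feature `"amplitude"` or `"latency"`.
#' @return List with numeric vectors `x` (method A), `y` (method B) and
#'   `n_pairs`.
#' @export
paired_feature_series <- function(table_a, table_b, peak,
                                  feature = c("amplitude", "latency")) {
  feature <- match.arg(feature)
  if (nrow(table_a) != nrow(table_b))
    stop("detection tables have different numbers of trials", call. = FALSE)
  lp <- tolower(peak)
  col <- paste0(lp, if (feature == "amplitude") "_amp" else "_lat")
  both <- table_a[[paste0(lp, "_pres")]] == 1L & table_b[[paste0(lp, "_pres")]] == 1L
  list(x = table_a[[col]][both], y = table_b[[col]][both], n_pairs = sum(both))
}

#' Bland-Altman bias and limits of agreement
#'
#' The bias is the absolute mean difference (systematic error) and the limits
#' of agreement are `bias +/- 1.96 * SD` of the differences (random error),
#' reported as absolute values; `loa` is the larger of the two bounds, the
#' single-number summary of the maximum discrepancy to expect between the
#' methods.
#'
#' @param x,y Paired feature values (length >= 2).
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `loa`,
#'   `mean_diff` (signed) and `n_pairs`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2)
    stop("Bland-Altman needs at least 2 paired values", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  bias <- abs(m)
  list(bias = bias, sd_diff = s,
       loa_lower = abs(bias - 1.96 * s), loa_upper = abs(bias + 1.96 * s),
       loa = max(abs(bias - 1.96 * s), abs(bias + 1.96 * s)),
       mean_diff = m, n_pairs = length(x))
}

#' Intraclass correlation: two-way, absolute agreement, single measures
#'
#' ICC(A,1) from the two-way mean-square decomposition with trials as rows and
#' the two methods as raters:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`, `k = 2`.
#'
#' @param x,y Paired feature values (length >= 2).
#' @return ICC value, or `NA` when the total variance is zero.
#' @export
icc_single_absolute <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("ICC needs at least 2 paired values", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  if (all(m == grand)) return(NA_real_)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Within-pair coefficient of variation (percent)
#'
#' Root-mean-square within-pair CV: per pair, the within-pair variance is
#' `s_i^2 = (x_i - y_i)^2 / 2` and the pair mean is `m_i = (|x_i| + |y_i|)/2`
#' (absolute magnitudes, so negative-amplitude peaks yield positive
#' denominators); `CV = 100 * sqrt(mean(s_i^2 / m_i^2))`. Pairs with zero mean
#' magnitude are dropped with a warning.
#'
#' @param x,y Paired feature values (length >= 1).
#' @return CV in percent, or `NA` when every pair is dropped.
#' @export
cv_within_pairs <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  m <- (abs(x) + abs(y)) / 2
  drop <- m == 0
  if (any(drop)) warning(sum(drop), " pair(s) with zero mean magnitude dropped")
  if (all(drop)) return(NA_real_)
  s2 <- (x - y)^2 / 2
  100 * sqrt(mean((s2 / m^2)[!drop]))
}

#' All agreement indices for one subject and one pairing
#'
#' Categorical indices are computed from the presence flags of all trials;
#' quantitative indices (Bland-Altman, ICC, CV) from the both-present trials
#' of each feature. Quantitative indices with fewer than 2 pairs are `NA`.
#'
#' @param table_a,table_b [detection_table()]s of the same subject.
#' @return Data frame with columns `peak`, `feature`, `index`, `value`,
#'   `n_pairs` (categorical rows have `feature = "presence"` and
#'   `n_pairs = n` trials).
#' @export
agreement_indices <- function(table_a, table_b) {
  rows <- list()
  for (pk in c("N1", "N2", "P2")) {
    lp <- tolower(pk)
    ct <- contingency(table_a[[paste0(lp, "_pres")]],
                      table_b[[paste0(lp, "_pres")]])
    cat <- categorical_agreement(ct)
    for (ix in c("p_o", "p_pos", "p_neg", "p_e", "kappa")) {
      rows[[length(rows) + 1L]] <-
        data.frame(peak = pk, feature = "presence", index = ix,
                   value = cat[[ix]], n_pairs = ct$n)
    }
    for (ft in c("amplitude", "latency")) {
      pr <- paired_feature_series(table_a, table_b, pk, ft)
      q <- if (pr$n_pairs >= 2) {
        ba <- bland_altman(pr$x, pr$y)
        c(bias = ba$bias, loa = ba$loa,
          icc = icc_single_absolute(pr$x, pr$y),
          cv = suppressWarnings(cv_within_pairs(pr$x, pr$y)))
      } else {
        c(bias = NA_real_, loa = NA_real_, icc = NA_real_, cv = NA_real_)
      }
      for (ix in names(q)) {
        rows[[length(rows) + 1L]] <-
          data.frame(peak = pk, feature = ft, index = ix, value = unname(q[[ix]]),
                     n_pairs = pr$n_pairs)
      }
    }
  }
  do.call(rbind, rows)
}
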