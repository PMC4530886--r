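# Group-level hypothesis tests: Friedman omnibus across conditions within
# subjects, Student-Newman-Keuls stepwise comparisons on mean ranks, and
# intensity-stratified index matrices.

#' Friedman test on a subjects x conditions index matrix
#'
#' Rows are subjects (blocks), columns are conditions (method pairings or
#' stimulation intensities). Rows containing missing values are dropped
#' listwise with a warning (the test requires complete blocks). The
#' tie-corrected chi-squared statistic and its asymptotic p value come from
#' [stats::friedman.test()]; within-row mean ranks are reported for post hoc
#' use.
#'
#' @param m Numeric matrix, subjects x conditions.
#' @return List of class `friedman_result` with `chi2`, `df`, `p`,
#'   `mean_ranks`, `n` (complete rows) and `k` (conditions).
#' @export
friedman_ranks <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (!all(complete))
    warning(sum(!complete), " subject(s) with missing values dropped listwise")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete subjects", call. = FALSE)
  ranks <- t(apply(m, 1, rank))
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(chi2)) {
    # every row fully tied: no information, by convention chi2 = 0, p = 1
    chi2 <- 0
    p <- 1
  }
  structure(list(chi2 = chi2, df = unname(ft$parameter),
                 p = p, mean_ranks = colMeans(ranks),
                 n = nrow(m), k = ncol(m)),
            class = "friedman_result")
}

#' Student-Newman-Keuls post hoc comparisons on Friedman mean ranks
#'
#' Conditions are ordered by mean rank and compared stepwise with the
#' studentized range: for a comparison spanning `p` ordered means, the
#' statistic `q = (Rbar_max - Rbar_min) / sqrt(k (k + 1) / (12 n))` is referred
#' to the studentized-range quantile with `p` means and infinite error degrees
#' of freedom. Per the SNK protection rule, once a range is declared
#' non-significant every comparison nested inside it is also declared
#' non-significant without testing.
#'
#' @param m Numeric subjects x conditions matrix (as for [friedman_ranks()]).
#' @param alpha Significance level of each stepwise test.
#' @return Data frame with one row per condition pair: `cond_i`, `cond_j`,
#'   `span`, `q`, `q_crit`, `significant`.
#' @export
snk_posthoc <- function(m, alpha = 0.05) {
  fr <- friedman_ranks(m)
  k <- fr$k
  n <- fr$n
  se <- sqrt(k * (k + 1) / (12 * n))
  ord <- order(fr$mean_ranks)
  mr <- fr$mean_ranks[ord]
  labs <- names(mr) %||% colnames(m)[ord] %||% as.character(ord)

  sig <- matrix(NA, k, k)
  res <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      q_obs <- (mr[j] - mr[i]) / se
      q_crit <- stats::qtukey(1 - alpha, span, Inf)
      # protection: non-significance of any enclosing range is inherited
      blocked <- FALSE
      if (span < k) {
        for (ii in 1:(k - span)) {
          jj <- ii + span
          if (ii <= i && jj >= j && isFALSE(sig[ii, jj])) blocked <- TRUE
        }
      }
      s <- if (blocked) FALSE else q_obs > q_crit
      sig[i, j] <- s
      res[[length(res) + 1L]] <-
        data.frame(cond_i = labs[i], cond_j = labs[j], span = span,
                   q = q_obs, q_crit = q_crit, significant = s)
    }
  }
  do.call(rbind, res)
}

#' Per-intensity agreement index matrix for one pairing
#'
#' Computes one agreement index (Cohen's kappa of presence, or the
#' within-pair CV of a feature) per subject x stimulation intensity, using
#' only that intensity's trials, yielding the matrix analysed by
#' [friedman_ranks()] when stimulation intensity is the factor.
#'
#' @param tables_a,tables_b Named lists of per-subject [detection_table()]s
#'   (two methods; matching subjects and trial order).
#' @param peak `"N1"`, `"N2"` or `"P2"`.
#' @param index `"kappa"` or `"cv"`.
#' @param feature Feature for `index = "cv"` (`"amplitude"` or `"latency"`).
#' @return Numeric matrix, subjects x intensities (`NA` where undefined).
#' @export
stratify_by_intensity <- function(tables_a, tables_b, peak,
                                  index = c("kappa", "cv"),
                                  feature = "amplitude") {
  index <- match.arg(index)
  subjects <- names(tables_a)
  stopifnot(identical(subjects, names(tables_b)))
  codes <- sort(unique(unlist(lapply(tables_a, function(d) d$intensity))))
  lp <- tolower(peak)
  out <- matrix(NA_real_, nrow = length(subjects), ncol = length(codes),
                dimnames = list(subjects, paste0("I", codes)))
  for (s in seq_along(subjects)) {
    da <- tables_a[[s]]
    db <- tables_b[[s]]
    if (nrow(da) != nrow(db))
      stop("trial counts differ for subject ", subjects[s], call. = FALSE)
    for (ci in seq_along(codes)) {
      sel <- da$intensity == codes[ci]
      if (!any(sel)) next
      if (index == "kappa") {
        ct <- contingency(da[[paste0(lp, "_pres")]][sel],
                          db[[paste0(lp, "_pres")]][sel])
        out[s, ci] <- categorical_agreement(ct)$kappa
      } else {
        pr <- paired_feature_series(da[sel, ], db[sel, ], peak, feature)
        if (pr$n_pairs >= 1)
          out[s, ci] <- suppressWarnings(cv_within_pairs(pr$x, pr$y))
      }
    }
  }
  out
}
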