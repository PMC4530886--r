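# erpagree

Single-trial detection of event-related potential (ERP) peaks and
quantification of the agreement between detection methods.

## The problem

ERPs elicited by somatosensory electrical stimulation at the vertex (Cz)
typically show three characteristic deflections: a negative peak **N1** near
90 ms, a second negative deflection **N2** near 140 ms, and a positive
complex **P2** near 250 ms. Estimating the presence, amplitude and latency of
these peaks *per stimulus repetition* — rather than from the across-trial
average — preserves trial-to-trial physiological variability, but different
detection methods (human observers, automated algorithms) can disagree both
on whether a peak is present at all (categorical outcome) and on its
amplitude/latency values (quantitative outcome). This package implements two
classic automated single-trial detectors and the full agreement framework
needed to compare any two methods, plus a synthetic-ERP simulator with known
ground truth so every component can be validated end to end.

It is aimed at electrophysiologists comparing annotation pipelines, and at
methodologists who need chance-corrected agreement statistics for paired
binary + continuous outcomes.

## What is implemented

**DRIV** — derivative-based detection with fuzzy-zone weighting. Local
extrema are located where the first difference of the trace changes sign.
Each candidate extremum at latency *t* is weighted within a per-peak fuzzy
zone with center *c* (taken from the subject's average ERP) and boundaries
*b*:

    w(t) = 1 − ((t − c) / (b_side − c))²,   w = 0 outside the boundaries

and the admissible candidate (negative amplitude for N1/N2, positive for P2)
maximizing `|amplitude| · w` is selected. A minimum that wins both N1 and N2
is assigned to the nearer zone center and the other zone is re-searched; a
zone with no admissible candidate yields an absent peak.

**WVLT** — wavelet filtering plus multiple linear regression. Trials are
transformed with a continuous complex Morlet wavelet (bandwidth `f_b = 0.05`,
center frequency `f_0 = 6`), the across-trial mean power map is thresholded
into a binary mask, each trial is reconstructed from its masked coefficients
(inverse CWT), and each filtered trial is fitted by least squares against
regressors built from the filtered average ERP (each peak's zero-crossing-
bounded segment and its first derivative, arranged in two passes because N1
and N2 usually share a negative segment). Peaks are read off the fitted trace
in windows centred on the average-ERP latencies.

**Agreement.** For presence/absence, from the 2×2 table (a = both present,
b/c = discordant, d = both absent, n = total):

    p_o   = 100 (a + d) / n                      overall agreement
    p_pos = 100 · 2a / (2a + b + c)              positive specific agreement
    p_neg = 100 · 2d / (2d + b + c)              negative specific agreement
    p_e   = 100 [(a+b)(a+c) + (c+d)(b+d)] / n²   chance agreement
    κ     = max(0, (p_o − p_e) / (100 − p_e))    Cohen's kappa, floored at 0

For amplitudes/latencies on trials where *both* methods detect the peak:
Bland-Altman bias `|mean(x−y)|` and limits of agreement `bias ± 1.96·SD`
(reported as absolute values), the two-way absolute-agreement single-measure
intraclass correlation ICC(A,1), and the root-mean-square within-pair
coefficient of variation `CV = 100·sqrt(mean(s_i²/m_i²))` with
`s_i² = (x_i−y_i)²/2` and `m_i = (|x_i|+|y_i|)/2`.

**Group statistics.** Friedman tests (tie-corrected) across method pairings
or stimulation intensities on per-subject index samples, with
Student-Newman-Keuls stepwise post hoc comparisons on mean ranks.

**Simulator.** Gaussian-bump peaks with configurable polarity, latency
jitter, amplitude-vs-intensity slope and a logistic presence-probability
model over six graded stimulation intensities (0.50–2.00 × reflex
threshold), on AR(1)+white background noise; ground truth records the
realized extrema of the clean trace.

## Worked example

```r
library(erpagree)
cfg <- sim_config(n_subjects = 4, n_trials_per_intensity = 5, seed = 7)
res <- run_simulated_study(cfg)

subset(res$summary$detection_summary, quantity == "n_detected",
       select = c(method, peak, mean, sd))
#>    method peak  mean         sd
#> 3   TRUTH   N1 23.50  2.0816660
#> 6   TRUTH   N2 18.25  2.5000000
#> 9   TRUTH   P2 28.75  0.9574271
#> 12   DRIV   N1 24.75  2.6299556
#> 15   DRIV   N2 18.50  4.2031734
#> 18   DRIV   P2 30.00  0.0000000
#> 21   WVLT   N1 27.25  1.5000000
#> 24   WVLT   N2 19.75 13.2256065
#> 27   WVLT   P2 30.00  0.0000000

aggregate(value ~ pairing + peak,
          data = subset(res$agreement, index == "kappa"), FUN = median)
#>      pairing peak     value
#> 1  DRIV-WVLT   N1 0.4011858
#> 2 TRUTH-DRIV   N1 0.4088171
#> 3 TRUTH-WVLT   N1 0.4123049
#> 4  DRIV-WVLT   N2 0.2268628
#> 5 TRUTH-DRIV   N2 0.4403328
#> 6 TRUTH-WVLT   N2 0.2665855
#> 7 TRUTH-DRIV   P2 0.0000000
#> 8 TRUTH-WVLT   P2 0.0000000
```

Per method and peak, the first table gives the mean ± SD (across subjects) of
the number of trials in which the peak was detected out of 30; both detectors
call P2 in essentially every trial, so almost all of their P2 agreement is
chance agreement and the floored κ drops to 0 — the characteristic failure
mode of overall-percent-agreement reporting that the chance-corrected
indices expose. The medians of per-subject κ show moderate N1 agreement and
weaker N2 agreement (N1/N2 overlap makes the N2 call the hardest).

Detection on your own data needs only per-subject epoch matrices
(`detect_study_driv()`, `detect_study_wvlt()`) or per-trial detection tables
imported from the long-format CSV container (`read_detection_container()`,
one row per trial × peak: method, subject, trial, peak, present,
amplitude_uV, latency_ms, intensity_code).

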