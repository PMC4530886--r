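---
title: "Single-trial ERP detection and between-method agreement: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial ERP detection and between-method agreement: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model behind the synthetic generator, the two automated single-trial
detectors, the agreement framework, and the numerical and design decisions
taken where the underlying methods leave choices open.

## The signal model

A single-trial epoch is modelled as

$$x(t) = \sum_{p \in \{N1, N2, P2\}} z_p \, s_p A_p
\exp\!\left(-\frac{(t-\tau_p)^2}{2\sigma_p^2}\right) + \eta(t),$$

where $z_p \in \{0,1\}$ is a Bernoulli presence indicator, $s_p$ the
polarity ($-1$ for N1/N2, $+1$ for P2), $A_p > 0$ the drawn magnitude,
$\tau_p$ the drawn latency and $\eta$ background noise. Epochs span
$-200$ to $1800$ ms around stimulus onset at 2048 Hz (4096 samples).

Parameters and defaults (all per-peak values N1/N2/P2):

* **Mean latencies** 90/140/250 ms, latency jitter SD 10/10/15 ms.
* **Half-widths** 20/25/60 ms, interpreted as half-width at half-maximum
  ($\sigma_p = \mathrm{hw}_p / \sqrt{2\ln 2}$). Under this reading the N1 and
  N2 bumps overlap without a zero crossing between them — the hallmark of
  vertex recordings and the motivation for the WVLT two-pass scheme — while
  still producing two distinct minima at comparable amplitudes. Reading the
  half-width as the Gaussian SD instead makes the presence-weighted average
  N1/N2 complex collapse into a single minimum, which contradicts the premise
  that peak latencies can be identified on the average ERP at all.
* **Amplitudes** $A_p = \max(0.5, \mathcal{N}(b_p + m_p (r - 1), s^2_{A,p}))$
  with base magnitudes 15/15/20 µV at $r = 1$ (the reflex-threshold
  multiple), slopes 8/8/10 µV per unit $r$, jitter SD 3/3/4 µV. The 0.5 µV
  floor keeps present peaks non-degenerate.
* **Presence** follows a logistic in the intensity ratio,
  $\Pr(z_p = 1) = \mathrm{logit}^{-1}((r - r_{0,p})/s_p)$ with midpoints
  0.60/0.95/0.30 and scales 0.20/0.30/0.15. No per-intensity presence rates
  are available to calibrate against; these values were chosen once so that
  the *average* detection rates over the six intensities
  (0.50–2.00 × threshold) are roughly 80% (N1), 60% (N2) and 95% (P2),
  the qualitative ordering reported for this kind of recording.
* **Noise** is a mixture of an AR(1) process (lag-1 correlation 0.976,
  i.e. a spectral corner near 8 Hz at 2048 Hz) and white noise, 90%/10% of a
  total SD of 10 µV — band-limited background of the same order as the peaks,
  giving realistically imperfect single-trial detection.

**Ground truth** records, for every present peak, the latency and amplitude
of the *realized* extremum of the clean (noise-free) trace nearest the drawn
latency. Overlapping bumps shift each other's extrema by several
milliseconds, so the drawn template values are not what any detector can
recover; the realized extremum is. This definition makes "exact recovery on
noiseless data" a well-posed property.

**What the simulator does not emulate:** multi-channel topography, eye/muscle
artifacts, latency drift across blocks, non-Gaussian peak shapes, or
stimulus-locked oscillatory components. Passing tests on synthetic data
therefore validate the detectors' *mechanics* (extremum logic, masking,
regression, read-off) and the statistical framework, not their clinical
performance on recorded EEG.

## Preprocessing

Epochs are band-pass filtered 0.5–30 Hz and baseline-corrected by the
pre-stimulus mean. The filter applies the *squared Butterworth magnitude
response* in the frequency domain (order 4 per branch), on the demeaned
signal extended by even reflection. This is exactly zero phase — latencies
are never phase-shifted — and numerically robust where transfer-function IIR
coefficients become ill-conditioned (a 0.5 Hz corner at 2048 Hz is a
normalized cutoff of 5·10⁻⁴). The even extension removes the edge step that
plain zero-padding would introduce.

## DRIV

Extrema sit where the first difference changes sign; a plateau (a run of
exactly equal samples between opposite slopes) contributes its midpoint
sample — a deterministic convention, as is the earlier-latency rule for tied
weighted scores. The fuzzy weight is the two-sided quadratic
$w(t) = 1 - ((t-c)/(b_{side}-c))^2$, 1 at the zone center, 0 at and beyond
the boundaries. Zone centers come from the subject's average ERP (largest
correct-polarity extremum within per-peak search windows of 50–130, 110–200
and 180–400 ms); boundary half-widths default to ±35/±35/±70 ms. A minimum
that is the top candidate of both N1 and N2 goes to the nearer zone center
and the other zone is re-searched among the remaining minima. Two residual
conventions are ours: if the final N1/N2 latencies come out reversed
(possible when zones overlap), the assignments are swapped so N1 precedes
N2; and when the average ERP lacks a distinct extremum for some peak, the
study driver falls back to the nominal window midpoint as the zone center
(the automated counterpart of manual centering; `zones_from_average()`
errors instead unless asked to fall back).

## WVLT

The analytic Morlet wavelet
$\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_0 t} e^{-t^2/f_b}$ with
$f_b = 0.05$, $f_0 = 6$ has the Fourier transform
$e^{-\pi^2 f_b (f - f_0)^2}$; the kernel for analysis frequency $f_k$ is its
L2-normalised dilation by $a_k = f_0/f_k$, applied by FFT on the zero-padded
epoch.

Numerical choices, each made once on first principles:

* **Frequency grid:** log-spaced 0.25–30 Hz, 16 voices per octave. Two
  considerations force a log grid reaching below the nominal 0.5 Hz band
  edge. First, the Morlet bandwidth scales with frequency (≈ $f/6$ here), so
  a linear grid undersamples the kernels at low frequency and the inverse
  transform's gain ripples strongly below ~3 Hz; log spacing keeps kernel
  density proportional to bandwidth and the gain flat. Second, Gaussian
  bumps have low-pass spectra: truncating the grid at 1 Hz discards ~13–15%
  of the wide P2 bump's amplitude, while 0.25 Hz keeps reconstruction error
  within a few percent.
* **Inverse transform:** single-integral (delta) reconstruction
  $\hat{x}(t) = C \sum_k w_k \,\mathrm{Re}\, W(f_k, t)$ with
  $w_k = \Delta\ln f_k \sqrt{f_k}$. The constant $C$ is calibrated from the
  bank's closed-form response to an in-band sinusoid (the median response
  over interior grid frequencies), making the all-ones-mask round trip unit
  gain by construction.
* **Analysis rate:** epochs are low-pass filtered (zero phase) and decimated
  to 256 Hz before the transform. All analysis content is below 30 Hz, and
  the read-off grid of ~3.9 ms is well below the 5 ms accuracy the package
  tests for; this keeps a 16-subject study's transform inside seconds rather
  than hours. Configurable via `analysis_rate`.
* **Mask threshold:** cells of the across-trial mean power map at or above
  5% of its maximum are kept (`threshold = 0.05`). The rule is
  scale-free; the value is a denoising choice with a real trade-off. A 5%
  power mask removes the weak high-frequency content that encodes the notch
  between overlapping N1 and N2 even in noise-free data (merging their
  minima in the filtered average) — which is precisely the overlapping-peak
  weakness this class of wavelet filters is known for, so the default keeps
  it. Tests of transform/regression/read-off *fidelity* use 0.005, a mask
  that passes the complete noise-free signal support.
* **Read-off windows:** ±25 ms for N1/N2, ±100 ms for P2, centred on the
  filtered-average latencies. The N window must stay narrower than the
  ~50 ms N1–N2 separation: a wider window spans both negative peaks and the
  extremum read-off returns whichever is deeper, producing ~40 ms latency
  errors for the shallower peak.
* **Two passes and P2:** pass A fits {N1, P2}, pass B {N2, P2}, since N1 and
  N2 usually share one zero-crossing-bounded negative segment. How the two
  P2 estimates should be combined is not specified by the method; P2 is read
  from pass A (falling back to pass B), a deterministic choice that
  coincides with pass B's estimate whenever the positive segment is shared.
* **Absence:** a peak is absent in a trial when no sample of the correct
  polarity exists in its read-off window of the fitted trace — the minimal
  absence rule for a method that otherwise always returns a fit. When the
  filtered average lacks a distinct extremum for a peak, the study driver
  substitutes the nominal window midpoint (polarity permitting), mimicking
  the manual latency selection the original procedure relies on; peaks whose
  window has the wrong polarity are reported absent for that subject.
* **Edges:** the CWT zero-pads; no cone-of-influence masking is applied. The
  ERP support sits hundreds of milliseconds from the epoch edges, where edge
  effects for kernels down to 0.25 Hz (temporal SD ≈ 3.8 s at that
  frequency) matter only for sustained, not transient, components.

## Agreement indices

Categorical indices are computed on the 0–100 scale with
$\kappa = \max(0, (p_o - p_e)/(100 - p_e))$ — the zero floor is applied
exactly as in the reporting convention this framework follows, and κ is
undefined (missing) when $p_e = 100$ (a method pair with fully degenerate
marginals). $p_{pos}$/$p_{neg}$ are missing when no positive, respectively
negative, call exists on either side.

Quantitative indices use only trials where **both** methods report the peak
present — a difference is undefined otherwise. Bias and limits of agreement
are reported as absolute values (the question is how large discrepancies
are, not their direction); the single-number `loa` summary is the larger
bound. ICC is the two-way absolute-agreement single-measure form
$(MS_R - MS_E)/(MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E))$, $k = 2$. The
CV is the root-mean-square within-pair form with pair means taken on
absolute amplitudes so negative peaks have positive denominators; the exact
CV convention is a known source of small between-implementation differences,
and pairs with zero mean magnitude are dropped with a warning.

## Group statistics

Per-subject index samples (one value per subject per condition) enter a
tie-corrected Friedman test (`stats::friedman.test`; fully tied matrices are
reported as χ² = 0, p = 1 rather than undefined). Post hoc comparisons use
the Student-Newman-Keuls stepwise procedure *on the Friedman mean ranks*,
with standard error $\sqrt{k(k+1)/(12n)}$ and studentized-range critical
values at infinite degrees of freedom; once a range is non-significant all
nested comparisons inherit non-significance. Running SNK on ranks rather
than raw index values keeps the post hoc scale consistent with the rank-based
omnibus test — the alternative (raw values) can shift individual post hoc
calls but not the Friedman statistics. Subjects with missing index values
(e.g. an undefined CV) are dropped listwise with a warning, since Friedman
requires complete blocks.

Intensity-stratified analyses recompute κ or CV per subject × intensity from
only that intensity's ~20 trials, giving the subjects × 6 matrix the same
machinery tests.

## Degenerate inputs and error behaviour

Containers with wrong column counts, presence flags outside {0, 1} or
inconsistent trial sets fail with messages naming the offending
subject/row. Absent peaks' amplitude/latency fields are treated as missing
on read regardless of stored placeholder (the writer stores NA). Bland-Altman
and ICC require ≥ 2 pairs; rank-deficient regression designs are reported
with the collinear columns named; read-off windows outside the epoch and
analysis frequencies at or above Nyquist are rejected.

## Problem sizes used by the test suite

The suite validates properties at deliberately chosen scales: brute-force
detector equivalence on 1000 random 500-sample traces; limits-of-agreement
coverage and SD recovery at n = 10 000 pairs; presence-rate calibration at
n = 10 000 simulated trials (128 Hz epochs — presence logic is rate
independent); Friedman type-I error over 10 000 null replicates at the study
geometry (16 subjects × 6 conditions) and a 10 000-draw permutation oracle
for its p value; full-pipeline recovery and determinism on 2–4-subject
studies. The acceptance script runs the complete default-scale study
(16 × 120 trials at 2048 Hz).

## Known limitations

* The original detectors' exact configurations (fuzzy-zone boundaries, mask
  threshold, read-off windows, frequency grid) are not published; numeric
  parity with those implementations is not claimable, only faithfulness to
  the described rules.
* The WVLT absence rule and the automated stand-in for its manual
  latency-selection step are this package's reconstructions of underspecified
  steps; both are documented above and configurable.
* Agreement indices are computed per subject; subjects in which an index is
  undefined (degenerate marginals, no both-present trials) reduce the group
  test's n by listwise deletion.
* The simulator's presence model and noise parameters are qualitative
  stand-ins, not fits to recorded data; absolute agreement levels obtained on
  synthetic studies should not be read as predictions for real recordings.
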