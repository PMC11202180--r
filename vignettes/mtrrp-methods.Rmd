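---
title: "Multi-threshold recurrence analysis: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-threshold recurrence analysis: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrrp)
```

## The construct

A recurrence plot of a scalar series $x_1,\dots,x_n$ is built from the
time-delay embedding $X_i = (x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$
and a threshold $\varepsilon$:

$$R_{ij} = \mathbf{1}\{\,d(X_i, X_j) \le \varepsilon\,\},$$

with $d$ the Euclidean norm by default. The recurrence rate
$\mathrm{RR}(\varepsilon)$ is the fraction of ones among all counted
cells — the probability that two states of the trajectory lie within
$\varepsilon$ of each other. Any single $\varepsilon$ is a compromise;
this package instead records the whole function
$\varepsilon \mapsto \mathrm{RR}(\varepsilon)$ over the ladder

$$\varepsilon_k = \varepsilon_{\min} + k\,Q\,\sigma, \qquad k = 0, 1,
2, \dots \text{ while } \varepsilon_k \le 1,$$

computed on the series min-max normalized to $[0,1]$ (so thresholds are
fractions of the data range) with $\sigma$ the standard deviation of the
normalized series. The defaults $\varepsilon_{\min} = 0.1$ (10% of the
range), $Q = 0.3$ and $m = 2$ follow the usual recommendation for this
construction; $\tau$ is selected per series as the first lag at which
the autocorrelation function drops below $1/e$ (a mutual-information
first-minimum selector and a false-nearest-neighbour dimension selector
are also provided).

Three metrics summarize the curve.

**Recurrence Rate Gradient.** The OLS slope of
$\mathrm{RR}(\varepsilon)$ against $\varepsilon$ over the initial,
rising segment. The fit cutoff is either a uniform maximum threshold or,
by default, the per-series stabilization point: the smallest
$\varepsilon$ whose RR reaches 95% of the final RR. White noise
decorrelates immediately, so its recurrence count grows as fast as the
threshold ball can grow — a steep gradient is a signature of local
randomness.

**Recurrence Hurst.** The curve is read through the two-parameter model
$$\mathrm{RR}(\varepsilon) = \alpha\,(1 - \mathrm{RH}\,\log
\varepsilon),$$
whose inverse at a single threshold is
$\mathrm{RH} = (1 - \mathrm{RR}/\alpha)/\log\varepsilon$. Natural
logarithms are used throughout; the printed form of the model and its
inverse are only mutually consistent under this reading, which is the
one implemented. Each pre-plateau threshold yields one estimate $h_k$;
the median is reported (the mean is available) because the estimate
blows up as $\varepsilon \to 1$, where $\log \varepsilon \to 0$.
Thresholds within rounding distance of 1, and thresholds already at
$\mathrm{RR} = 1$, are skipped and counted in the diagnostics. Note the
sign convention: on normalized data $\log \varepsilon < 0$, so $h_k$ is
negative wherever $\mathrm{RR} < \alpha$. Values are reported exactly as
computed — no sign is flipped — and what carries information is the
ordering across signals: the fBm sweep in the test suite pins
$\mathrm{RH}$ to be monotone in the generator's Hurst exponent
(Spearman $|\rho| \ge 0.8$ across $H = 0.1, \dots, 0.9$).

**Recurrence Complexity.** The exact product
$\mathrm{RC} = \mathrm{RRG} \times \mathrm{RH}$, coupling local
randomness with long-range persistence.

## On the model constant $\alpha$

$\alpha$ is the model's value of RR extrapolated to $\varepsilon = 1$,
conventionally quoted as $0.5$ for classical Brownian motion. Under the
symmetric recurrence-rate definition used in this package — every cell
of the $n \times n$ matrix counted, so $\mathrm{RR} \to 1$ as
$\varepsilon$ grows, an invariant the brute-force oracle tests enforce —
the jointly fitted constant for simulated classical Brownian motion
comes out near $1.0$ (mean $\approx 1.02$ over 20 seeds at $n = 4096$),
i.e. twice the conventional value. The factor of two is exactly what
one obtains by counting each unordered pair once while normalizing by
$n^2$, a common implementation shortcut in recurrence software. The
package does not adopt that convention: RR here is a probability that
saturates at 1, and `scripts/acceptance.R` reports the fitted constant
as computed. Users comparing against half-matrix implementations should
halve it. The default $\alpha = 0.5$ is kept for the Recurrence Hurst
inverse because RH is used comparatively (its monotonicity in the
underlying persistence is what the tests pin down), and rescaling
$\alpha$ shifts all $h_k$ by a common monotone transformation at each
threshold.

## Epoching and computational contract

The recurrence computation is quadratic in the trajectory length. Long
recordings are therefore split into non-overlapping epochs of
`epoch_length` samples (default 2000, i.e. 4 s of 500 Hz EEG) and the
per-epoch recurrence rates are averaged per threshold; for stationary
signals the epoched and whole-series curves agree closely (tested).
Recurrence matrices themselves are only materialized up to a 5000-point
cap; above that, rates are accumulated by a compiled single-pass counter
that never stores the matrix. When $\tau$ is auto-selected it is capped
at one tenth of the epoch length: strongly persistent paths have $1/e$
autocorrelation lags comparable to the whole series, and an uncapped
delay would leave an epoch with too few embedded points to count. An
explicitly supplied $\tau$ bypasses the cap.

## Simulators

**Fractional Brownian motion** is generated by circulant embedding of
the fractional-Gaussian-noise covariance (exact to machine precision,
$O(n \log n)$), with a Cholesky fallback if the circulant eigenvalues go
negative (only relevant for small $n$ with $H$ near 1). The test suite
verifies the $k$-step increment variance scaling $k^{2H}$ and parameter
recovery by AFA.

**Reference signals**: i.i.d. Gaussian noise, its cumulative sum, a pure
sinusoid, and the logistic map at $r = 4$ with a fixed burn-in of 1000
iterations.

**Synthetic EEG.** Each channel is a sum of five band-limited sinusoidal
carriers (Delta 2 Hz, Theta 6 Hz, Alpha 10 Hz, Beta 20 Hz, Gamma 36 Hz,
with per-subject random phase and ±10% frequency jitter) plus a
fractional-Gaussian-noise background scaled to `noise_sd`. Default
amplitudes (20/10/15/5/2, `noise_sd` = 15, arbitrary µV-like units)
reflect the usual resting-state ordering with a dominant broadband
background. The group effect is injected only through the Hurst exponent
of the O1/O2 noise component (defaults 0.7 vs 0.3), so a real difference
in long-range temporal structure — and therefore in occipital Recurrence
Complexity — exists by construction. What the generator does **not**
emulate: volume conduction and inter-channel correlation, 1/f spectral
shape beyond what fGn provides, non-stationarity, eye/jaw artifacts, or
any disease physiology. A pipeline that separates these cohorts has
demonstrated sensitivity to planted differences in temporal persistence;
that is evidence of mechanical correctness, not of clinical validity on
real EEG.

## EEG feature pipeline

Recordings (19-channel 10–20 montage) are band-pass filtered per band
with a 4th-order zero-phase Butterworth filter (forward–backward, so no
band-dependent delay). Band edges are the conventional Delta 0.5–4,
Theta 4–8, Alpha 8–13, Beta 13–30, Gamma 30–45 Hz; a FullBand 0.5–45 Hz
is available but excluded from the default table so the layout stays
channels × 5 bands × 3 metrics (285 columns for 19 channels). Inputs are
expected to be pre-cleaned (artifact removal is deliberately out of
scope); analysis uses the first 300 s by default. Because every series
is min-max normalized before thresholding, features are invariant to
channel gain — exactly so for power-of-two rescalings, and to within the
flip of a handful of threshold-boundary pairs (≲ $10^{-2}$ on RC) for
arbitrary factors, since the recurrence threshold is a hard binary cut
on floating-point values.

## Classification protocol

For each held-out subject, features are ranked by $|r|$ (Pearson, 0/1
labels) on the training subjects only, the top $k = 50$ kept,
training-standardized, and a linear SVM ($C = 1$; kernel and cost are
configurable — the linear kernel is the conservative choice in the
285-features / tens-of-subjects regime) predicts the held-out subject.
Selection and standardization are recomputed inside every fold — and
inside every permutation — so the null distribution inherits every
overfitting opportunity of the real run. The permutation p-value uses
the +1 correction, $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_{\mathrm{perm}})$, bounded below by $1/(n_{\mathrm{perm}}+1)$. A
"global selection" flag reproduces the optimistic variant that selects
once on all rows; it is off by default. Ties in $|r|$ resolve to the
earlier column; zero-variance features rank last with a warning.

Group statistics use per-feature (or per-region-average) one-way ANOVA
with Bonferroni correction over the whole family, partial
$\eta^2 = F d_1 / (F d_1 + d_2)$, and Bonferroni-adjusted pairwise
post-hoc t comparisons.

## AFA

The Hurst exponent is estimated from the integrated profile $u$ by
fitting, at each odd window size $W = 2h+1$ of a dyadic ladder
($5, 9, 17, \dots \le n/8$), local polynomials (order 1 by default) on
windows overlapping by half, blended into a global trend $v$ with
triangular weights peaked at the window center — weights sum to one in
every regular overlap, which makes the stitched trend reproduce
polynomial inputs exactly (tested to $10^{-9}$). Then
$F(W) = \mathrm{rms}(u - v)$ and $\hat H$ is the OLS slope of $\log_2 F$
on $\log_2 W$. Whether the input is an increment series or a path must
be stated (`input_is_increments`); silently guessing would invite the
classic off-by-one-in-$H$ error, so it is the caller's explicit choice.
An exactly polynomial input has zero residuals everywhere and raises a
degenerate-fit error rather than returning an arbitrary slope.

## Numerical choices and degenerate inputs

- Constant series cannot be normalized (error), zero-variance normalized
  series admit no threshold ladder (error), ladders with fewer than
  three rungs suggest a smaller $Q$ (error).
- Curves saturated at $\mathrm{RR} = 1$ from the first threshold have no
  rising segment (fit error) and no usable Hurst information
  (degenerate-curve error).
- The Theiler window (default 0, so the line of identity is counted, as
  the plain RR definition implies) may exclude the diagonal band; a
  window that excludes every cell is an error, not a silent NaN.
- The joint $\alpha$/RH fit uses `nls` with a scale offset so that
  exactly model-generated curves (zero residual) converge cleanly.

## Problem sizes used by the test suite

Chosen as this package's own validation conventions: fBm validation at
$n = 8192$ with 20 seeds per condition (AFA recovery
$\overline{|\hat H - H|} \le 0.15$); the Recurrence Hurst sweep at
$n = 4096$, 20 seeds per $H$; brute-force oracle equivalence on 1000
random instances of up to 50 points; the end-to-end cohort at 15 + 15
subjects, 60-second 500 Hz recordings with occipital noise Hurst 0.7 vs
0.3, classified with $k = 50$ and a 99-shuffle permutation null. All
quantities asserted by the tests are computed at run time by the same
public functions documented here.

## Known limitations

- Only the recurrence rate is swept; diagonal- and vertical-line
  statistics (determinism, laminarity, entropy, trapping time) are not
  computed.
- The Recurrence Hurst is a comparative index, not a calibrated
  estimator of $H$: its values depend on $\alpha$, the ladder and the
  aggregation rule, and only its ordering is validated.
- EDF input is not parsed; recordings enter as in-memory matrices or
  plain CSV (`read_eeg_csv`).
- The classification module implements two-class tasks only; multi-group
  questions are handled by the ANOVA side or by collapsing groups.
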