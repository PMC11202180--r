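# mtrrp

Multi-threshold recurrence quantification for univariate time series and
resting-state EEG.

A recurrence plot marks the time pairs (i, j) at which a system's
phase-space trajectory returns to within a distance ε of itself; the
recurrence rate RR(ε) is the fraction of marked cells. Instead of fixing
one threshold, **mtrrp** sweeps a ladder of thresholds

&nbsp;&nbsp;&nbsp;&nbsp;ε_k = ε_min + k·Q·σ,&nbsp;&nbsp;k = 0, 1, 2, … (truncated at 1 on
min-max-normalized data, defaults ε_min = 0.1, Q = 0.3)

and studies the resulting curve RR(ε_k) — the *multi-threshold recurrence
rate plot* (MTRRP). Three scalar metrics summarize the curve:

- **Recurrence Rate Gradient (RRG)** — the OLS slope of the initial,
  pre-plateau segment of RR against ε. Noise-like signals accumulate
  recurrences quickly (steep slope); strongly persistent signals slowly.
- **Recurrence Hurst (RH)** — a Hurst-like exponent read off the curve
  through the model RR(ε) = α·(1 − RH·log ε) (natural log, default
  α = 0.5), aggregated by the median over the pre-plateau thresholds.
- **Recurrence Complexity (RC = RRG × RH)** — a joint index of local
  randomness and long-range persistence.

The package is aimed at researchers analyzing the nonlinear dynamics of
physiological recordings (the EEG tooling assumes the standard 19-channel
10–20 montage), and at anyone who wants threshold-resolved recurrence
analysis with a verified, brute-force-checked core. It also provides:

- exact-covariance simulation of fractional Brownian motion
  (circulant embedding / Davies–Harte, Cholesky fallback) and reference
  signals (white noise, random walk, harmonic, logistic chaos);
- adaptive fractal analysis (AFA) estimation of the Hurst exponent from
  the RMS residual of an adaptively stitched local-polynomial trend;
- a synthetic multi-channel EEG generator with a controllable occipital
  group effect, used to validate the whole pipeline end to end;
- Butterworth band-pass feature extraction over the conventional Delta /
  Theta / Alpha / Beta / Gamma bands into a subjects × (channel, band,
  metric) table (19 × 5 × 3 = 285 columns);
- a leakage-safe SVM leave-one-out protocol (per-fold Pearson feature
  selection and standardization) with a label-permutation null, plus
  per-feature one-way ANOVA with Bonferroni correction and partial
  eta squared.

## Worked example

```r
library(mtrrp)

# Fractional Brownian motion: persistent (H = 0.8) vs anti-persistent
x_pers <- generate_fbm(hurst = 0.8, n = 4096, seed = 1)
x_anti <- generate_fbm(hurst = 0.2, n = 4096, seed = 1)

mtrrp_metrics(x_pers)
#> MTRRP metrics: RRG = 1.2486, RH = 0.4134, RC = 0.5161
mtrrp_metrics(x_anti)
#> MTRRP metrics: RRG = 1.9551, RH = 0.3031, RC = 0.5926

# the anti-persistent signal has the steeper initial slope (more
# noise-like locally) and the lower Recurrence Hurst; the independent
# AFA estimator recovers the planted Hurst exponents from the paths:
afa_fit(x_pers)
#> AFA fit: H = 0.810 (R^2 = 1.000) over 7 windows [5, 257]
afa_fit(x_anti)
#> AFA fit: H = 0.223 (R^2 = 0.999) over 7 windows [5, 257]
```

A full cohort run — synthetic 19-channel EEG with a planted occipital
group difference, feature table, classification, permutation null:

```r
cohort <- generate_synthetic_eeg(n_per_group = 15, duration = 60,
                                 occipital_hurst_by_group = c(HC = 0.7,
                                                              AD = 0.3),
                                 seed = 42)
ft <- extract_features(cohort, max_seconds = 60)  # 30 x 285 features
svm_loocv(ft, k = 50, seed = 7)
#> SVM-LOOCV (n = 30, k = 50, linear kernel): accuracy 100.0%,
#>   recall 100.0%, specificity 100.0%
permutation_test(ft, n_perm = 99, k = 50, seed = 7)
#> Permutation test: observed accuracy 100.0%, null mean 45.9%,
#>   p = 0.01 (99 shuffles)
```

The planted effect (noise Hurst 0.7 vs 0.3 in O1/O2) separates the
groups in the occipital Recurrence Complexity columns and is recovered
by the classifier, while shuffling the labels drops the protocol to
chance — the permutation p-value is bounded below by 1/(n_perm + 1).

Command-line wrappers for the main entry points live in `inst/cli/`
(`simulate.R`, `mtrrp.R`, `afa.R`, `classify.R`); each prints a JSON
report.

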