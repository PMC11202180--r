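# Independent brute-force oracles used to pin the fast implementations.

# Double-loop recurrence matrix: no vectorization, no shared code with the
# package internals.
oracle_recurrence_matrix <- function(ps, epsilon, norm = "euclidean",
                                     theiler = 0L) {
  if (is.null(dim(ps))) ps <- matrix(as.numeric(ps), ncol = 1L)
  n <- nrow(ps)
  rm <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < theiler) next
      d <- if (norm == "euclidean") {
        sqrt(sum((ps[i, ] - ps[j, ])^2))
      } else {
        max(abs(ps[i, ] - ps[j, ]))
      }
      if (d <= epsilon) rm[i, j] <- 1L
    }
  }
  rm
}

oracle_recurrence_rate <- function(ps, epsilon, norm = "euclidean",
                                   theiler = 0L) {
  if (is.null(dim(ps))) ps <- matrix(as.numeric(ps), ncol = 1L)
  n <- nrow(ps)
  ones <- 0L
  counted <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < theiler) next
      counted <- counted + 1L
      d <- if (norm == "euclidean") {
        sqrt(sum((ps[i, ] - ps[j, ])^2))
      } else {
        max(abs(ps[i, ] - ps[j, ]))
      }
      if (d <= epsilon) ones <- ones + 1L
    }
  }
  ones / counted
}

# Variance-scaling Hurst oracle: var of k-step increments of an fBm path
# grows as k^(2H); regress log variance on log k over dyadic lags.
oracle_hurst_varscaling <- function(path, lags = 2^(0:6)) {
  v <- vapply(lags, function(k) stats::var(diff(path, lag = k)), numeric(1))
  unname(stats::coef(stats::lm(log(v) ~ log(lags)))[2] / 2)
}

# Exact MTRRP model curve for round-trip tests: a curve object whose rates
# follow RR(eps) = alpha * (1 - rh * log eps) exactly.
model_curve <- function(thresholds, alpha, rh) {
  structure(list(
    thresholds = thresholds,
    rates = alpha * (1 - rh * log(thresholds)),
    sigma = NA_real_, m = 1L, tau = 1L,
    eps_min = thresholds[1], q = NA_real_,
    alpha = alpha, n_epochs = 1L,
    norm = "euclidean", theiler = 0L
  ), class = "mtrrp_curve")
}

# Tiny deterministic cohort for feature-table tests: short recordings at a
# reduced sampling rate keep the quadratic recurrence cost negligible.
tiny_cohort <- function(n_per_group = 1L, seed = 5L, duration = 8,
                        sampling_rate = 250) {
  generate_synthetic_eeg(
    n_per_group = n_per_group,
    occipital_hurst_by_group = c(HC = 0.7, AD = 0.3),
    sampling_rate = sampling_rate, duration = duration, seed = seed)
}
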