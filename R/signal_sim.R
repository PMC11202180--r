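#' Standard 19-channel 10-20 montage
#'
#' Channel names of the 19-electrode international 10-20 scalp montage used
#' throughout the package, in conventional anterior-to-posterior order.
#'
#' @return Character vector of 19 channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
    "Cz", "C3", "C4", "T3", "T4", "T5", "T6",
    "Pz", "P3", "P4", "O1", "O2")
}

# Autocovariance of fractional Gaussian noise with unit-variance increments:
# gamma(k) = 0.5 * (|k+1|^2H - 2|k|^2H + |k-1|^2H).
fgn_autocov <- function(k, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

# Simulate n samples of fractional Gaussian noise by circulant embedding
# (Davies-Harte). Exact covariance; O(n log n). Falls back to a Cholesky
# factorization of the n x n covariance matrix if the circulant eigenvalues
# are not all non-negative (can occur for small n with H near 1).
simulate_fgn <- function(n, hurst) {
  g <- fgn_autocov(0:n, hurst)
  row <- c(g, g[n:2]) # circulant first row, length 2n
  lambda <- Re(stats::fft(row))
  m <- 2L * n
  if (all(lambda > -1e-10)) {
    lambda <- pmax(lambda, 0)
    w <- complex(length.out = m)
    u <- stats::rnorm(m)
    v <- stats::rnorm(m)
    w[1] <- sqrt(lambda[1]) * u[1]
    w[n + 1] <- sqrt(lambda[n + 1]) * u[n + 1]
    idx <- 2:n
    w[idx] <- sqrt(lambda[idx] / 2) * complex(real = u[idx], imaginary = v[idx])
    w[m + 2 - idx] <- Conj(w[idx])
    x <- Re(stats::fft(w, inverse = FALSE)) / sqrt(m)
    x[seq_len(n)]
  } else {
    gam <- fgn_autocov(abs(outer(seq_len(n), seq_len(n), "-")), hurst)
    L <- chol(gam)
    as.numeric(crossprod(L, stats::rnorm(n)))
  }
}

#' Simulate fractional Brownian motion
#'
#' Generates a fractional Brownian motion (fBm) path with a given Hurst
#' exponent by exact-covariance circulant embedding of its fractional
#' Gaussian noise increments, followed by cumulative summation. H = 0.5
#' gives classical Brownian motion; H > 0.5 persistent and H < 0.5
#' anti-persistent increments.
#'
#' @param hurst Hurst exponent, strictly between 0 and 1.
#' @param n Number of samples (at least 64).
#' @param seed Integer seed; the generator is a pure function of
#'   (hurst, n, seed).
#' @return Numeric vector of length `n`: the fBm path (the increments are
#'   stationary Gaussian with unit variance at lag 1).
#' @examples
#' x <- generate_fbm(hurst = 0.5, n = 256, seed = 1)
#' @export
generate_fbm <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n < 64) stop("`n` must be at least 64", call. = FALSE)
  with_seed(seed, cumsum(simulate_fgn(as.integer(n), hurst)))
}

#' Generate reference test signals
#'
#' Canonical signal classes used to exercise recurrence analysis: stochastic
#' (white noise, random walk), harmonic oscillation, and deterministic chaos
#' (logistic map at r = 4, fully chaotic regime).
#'
#' @param kind One of "white_noise", "random_walk", "harmonic",
#'   "logistic_chaos".
#' @param n Number of samples (at least 64).
#' @param params List of kind-specific parameters: `period` (samples) for
#'   "harmonic"; ignored otherwise.
#' @param seed Integer seed (unused for "harmonic").
#' @return Numeric vector of length `n`.
#' @export
generate_reference <- function(kind, n, params = list(), seed = 1L) {
  if (n < 64) stop("`n` must be at least 64", call. = FALSE)
  n <- as.integer(n)
  switch(kind,
    white_noise = with_seed(seed, stats::rnorm(n)),
    random_walk = with_seed(seed, cumsum(stats::rnorm(n))),
    harmonic = {
      period <- params$period %||% 64
      if (period <= 1) stop("`period` must exceed 1 sample", call. = FALSE)
      sin(2 * pi * (seq_len(n) - 1) / period)
    },
    logistic_chaos = with_seed(seed, {
      burn_in <- 1000L
      x <- stats::runif(1, 0.1, 0.9)
      out <- numeric(n)
      for (i in seq_len(burn_in)) x <- 4 * x * (1 - x)
      for (i in seq_len(n)) {
        x <- 4 * x * (1 - x)
        out[i] <- x
      }
      out
    }),
    stop(sprintf("unknown reference signal kind '%s'", kind), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default per-band oscillation amplitudes for synthetic EEG
#'
#' Amplitudes (arbitrary microvolt-like units) of the five band-limited
#' carriers summed into each synthetic channel. The defaults reflect the
#' usual resting-state power ordering (prominent posterior alpha, strong
#' slow activity, weak gamma).
#'
#' @return Named numeric vector over Delta, Theta, Alpha, Beta, Gamma.
#' @export
default_band_amplitudes <- function() {
  c(Delta = 20, Theta = 10, Alpha = 15, Beta = 5, Gamma = 2)
}

# Band-typical carrier frequencies (Hz) for the synthetic oscillations.
band_carrier_freqs <- c(Delta = 2, Theta = 6, Alpha = 10, Beta = 20, Gamma = 36)

#' Simulate a synthetic multi-channel EEG cohort
#'
#' Builds a two-group (or multi-group) cohort of 19-channel recordings in
#' which every channel is a sum of five band-limited sinusoidal carriers
#' (with per-subject random phase and slight frequency jitter) plus a
#' fractional-Gaussian-noise background whose Hurst exponent is the
#' controllable quantity. In the occipital channels (O1, O2) the noise
#' Hurst is taken from `occipital_hurst_by_group`, injecting a real,
#' known group difference in long-range temporal structure by
#' construction; all other channels share `background_hurst`.
#'
#' @param n_per_group Subjects per group.
#' @param groups Ordered character vector of group labels.
#' @param occipital_hurst_by_group Named numeric vector (names = groups) of
#'   the Hurst exponent used for the O1/O2 noise component, each in (0, 1).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 300, i.e. the
#'   5-minute resting-state segment conventional in clinical EEG).
#' @param channels Channel names; defaults to the 19-channel 10-20 montage.
#' @param band_amplitudes Named amplitudes of the five carriers, see
#'   [default_band_amplitudes()].
#' @param noise_sd Standard deviation of the broadband noise component
#'   (same units as the carriers; default 15, i.e. comparable to the total
#'   oscillatory power, as in resting EEG where the 1/f background
#'   dominates).
#' @param background_hurst Noise Hurst for non-occipital channels
#'   (default 0.5).
#' @param occipital_channels Channels receiving the group-specific noise
#'   Hurst (default O1, O2).
#' @param seed Integer seed; identical specs and seeds give byte-identical
#'   cohorts.
#' @return List of recordings, one per subject; each is a list with
#'   `subject_id`, `group`, `sampling_rate`, and `data` (numeric matrix,
#'   samples x channels, with channel names as column names).
#' @export
generate_synthetic_eeg <- function(n_per_group,
                                   groups = c("HC", "AD"),
                                   occipital_hurst_by_group = c(HC = 0.7, AD = 0.3),
                                   sampling_rate = 500,
                                   duration = 300,
                                   channels = montage_1020(),
                                   band_amplitudes = default_band_amplitudes(),
                                   noise_sd = 15,
                                   background_hurst = 0.5,
                                   occipital_channels = c("O1", "O2"),
                                   seed = 1L) {
  n_samp <- as.integer(round(sampling_rate * duration))
  if (n_samp < 256L) {
    stop("duration x sampling_rate must give at least 256 samples",
         call. = FALSE)
  }
  if (!all(groups %in% names(occipital_hurst_by_group))) {
    stop("`occipital_hurst_by_group` must name every group", call. = FALSE)
  }
  hv <- occipital_hurst_by_group[groups]
  if (any(hv <= 0 | hv >= 1)) {
    stop("occipital Hurst values must lie strictly in (0, 1)", call. = FALSE)
  }
  bands <- names(band_carrier_freqs)
  if (!all(bands %in% names(band_amplitudes))) {
    stop("`band_amplitudes` must name Delta, Theta, Alpha, Beta, Gamma",
         call. = FALSE)
  }
  tt <- (seq_len(n_samp) - 1) / sampling_rate
  subjects <- vector("list", n_per_group * length(groups))
  k <- 0L
  for (g in seq_along(groups)) {
    for (s in seq_len(n_per_group)) {
      k <- k + 1L
      sseed <- child_seed(seed, k)
      data <- with_seed(sseed, {
        mat <- matrix(0, nrow = n_samp, ncol = length(channels),
                      dimnames = list(NULL, channels))
        for (ch in channels) {
          sig <- numeric(n_samp)
          for (b in bands) {
            f <- band_carrier_freqs[[b]] * stats::runif(1, 0.9, 1.1)
            phase <- stats::runif(1, 0, 2 * pi)
            sig <- sig + band_amplitudes[[b]] * sin(2 * pi * f * tt + phase)
          }
          h <- if (ch %in% occipital_channels) {
            occipital_hurst_by_group[[groups[g]]]
          } else {
            background_hurst
          }
          noise <- simulate_fgn(n_samp, h)
          sig <- sig + noise_sd * noise / stats::sd(noise)
          mat[, ch] <- sig
        }
        mat
      })
      subjects[[k]] <- list(
        subject_id = sprintf("sub-%02d", k),
        group = groups[g],
        sampling_rate = sampling_rate,
        data = data
      )
    }
  }
  subjects
}
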