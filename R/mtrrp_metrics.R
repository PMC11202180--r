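#' Min-max normalization to the unit interval
#'
#' Rescales a series to `[0, 1]` by (x - min) / (max - min), so that the
#' recurrence threshold ladder can be expressed in normalized units.
#' Idempotent: normalizing twice changes nothing.
#'
#' @param series Numeric vector with max > min.
#' @return Numeric vector in `[0, 1]` with both endpoints attained.
#' @export
normalize_unit <- function(series) {
  check_series(series)
  rng <- range(series)
  if (rng[1] == rng[2]) {
    stop("constant series cannot be normalized (max == min)", call. = FALSE)
  }
  (series - rng[1]) / (rng[2] - rng[1])
}

#' Threshold schedule for an MTRRP
#'
#' Builds the increasing ladder of recurrence thresholds
#' eps_k = eps_min + k * Q * sigma, k = 0, 1, 2, ..., truncated at 1.0,
#' where sigma is the standard deviation of the normalized series. The
#' step is proportional to sigma so the ladder adapts to the variability
#' of the data.
#'
#' @param series_normalized Series already normalized to `[0, 1]`.
#' @param eps_min Initial threshold in normalized units (default 0.1, i.e.
#'   10% of the data range).
#' @param q Increment factor (default 0.3).
#' @return Numeric vector of thresholds, strictly increasing, all in
#'   (0, 1]; attribute `sigma` carries the standard deviation used.
#' @export
build_schedule <- function(series_normalized, eps_min = 0.1, q = 0.3) {
  check_series(series_normalized)
  if (min(series_normalized) < -1e-9 || max(series_normalized) > 1 + 1e-9) {
    stop("`series_normalized` must lie in [0, 1]; call normalize_unit() first",
         call. = FALSE)
  }
  if (eps_min <= 0 || eps_min > 1) {
    stop("`eps_min` must lie in (0, 1]", call. = FALSE)
  }
  if (q <= 0) stop("`q` must be positive (no threshold progression)",
                   call. = FALSE)
  sigma <- stats::sd(series_normalized)
  if (sigma == 0) stop("degenerate series: zero standard deviation",
                       call. = FALSE)
  step <- q * sigma
  k_max <- floor((1 - eps_min) / step + 1e-9)
  thresholds <- eps_min + (0:k_max) * step
  if (length(thresholds) < 3L) {
    stop(sprintf(paste0(
      "only %d thresholds fit in (0, 1] with eps_min = %g, Q = %g, ",
      "sigma = %.3g; use a smaller Q"),
      length(thresholds), eps_min, q, sigma), call. = FALSE)
  }
  structure(thresholds, sigma = sigma)
}

#' Multi-threshold recurrence rate curve
#'
#' Core construction: the series is min-max normalized, a threshold ladder
#' is built from its standard deviation, and the recurrence rate of the
#' time-delay-embedded trajectory is evaluated at every threshold. For
#' long series the computation is epoched: the normalized series is split
#' into non-overlapping epochs and the per-epoch recurrence rates are
#' averaged per threshold, keeping the quadratic cost bounded.
#'
#' @param series Numeric vector (raw units; normalization is internal).
#' @param m Embedding dimension (default 2).
#' @param tau Delay in samples; `NULL` (default) selects it by the
#'   autocorrelation 1/e criterion (falling back to 1 for series too short
#'   or too irregular for the criterion).
#' @param eps_min,q Ladder parameters, see [build_schedule()].
#' @param norm Distance norm, see [recurrence_matrix()].
#' @param theiler Theiler exclusion (default 0).
#' @param epoch_length Epoch size in samples (default 2000); series at most
#'   this long are processed whole. `Inf` disables epoching.
#' @param alpha Model constant of the recurrence-rate model
#'   RR = alpha * (1 - RH * log eps) carried by the curve for later
#'   Recurrence Hurst extraction (default 0.5, the classical-Brownian
#'   value).
#' @return Object of class `mtrrp_curve`: list with `thresholds`, `rates`
#'   (non-decreasing, in `[0, 1]`), `sigma`, `m`, `tau`, `alpha`,
#'   `n_epochs`, `norm`, `theiler`.
#' @export
mtrrp_curve <- function(series, m = 2L, tau = NULL, eps_min = 0.1, q = 0.3,
                        norm = c("euclidean", "chebyshev"), theiler = 0L,
                        epoch_length = 2000L, alpha = 0.5) {
  norm <- match.arg(norm)
  check_series(series, min_len = 8L)
  x <- normalize_unit(series)
  thresholds <- build_schedule(x, eps_min = eps_min, q = q)
  if (is.null(tau)) {
    # the 1/e crossing stabilizes within a few thousand samples; bounding
    # the ACF input keeps delay selection cheap on long recordings
    tau <- tryCatch(
      select_delay(x[seq_len(min(length(x), 4096L))], "autocorrelation"),
      error = function(e) 1L)
    # a delay beyond a small fraction of an epoch starves the embedding
    tau <- max(1L, min(tau, floor(min(length(x), epoch_length) / 10)))
  }
  n <- length(x)
  if (is.finite(epoch_length) && n > epoch_length) {
    starts <- seq.int(1L, n - epoch_length + 1L, by = epoch_length)
    epochs <- lapply(starts, function(s) x[s:(s + epoch_length - 1L)])
  } else {
    epochs <- list(x)
  }
  rate_mat <- vapply(epochs, function(ep) {
    ps <- embed_series(ep, m, tau)
    recurrence_rates_at(ps, thresholds, norm = norm, theiler = theiler)
  }, numeric(length(thresholds)))
  rates <- rowMeans(matrix(rate_mat, nrow = length(thresholds)))
  structure(list(
    thresholds = as.numeric(thresholds),
    rates = rates,
    sigma = attr(thresholds, "sigma"),
    m = as.integer(m), tau = as.integer(tau),
    eps_min = eps_min, q = q,
    alpha = alpha,
    n_epochs = length(epochs),
    norm = norm, theiler = as.integer(theiler)
  ), class = "mtrrp_curve")
}

#' @export
print.mtrrp_curve <- function(x, ...) {
  cat(sprintf(
    "MTRRP curve: %d thresholds in [%.3g, %.3g], m = %d, tau = %d, %s norm\n",
    length(x$thresholds), min(x$thresholds), max(x$thresholds),
    x$m, x$tau, x$norm))
  cat(sprintf("  RR range [%.3f, %.3f] over %d epoch(s)\n",
              min(x$rates), max(x$rates), x$n_epochs))
  invisible(x)
}

#' @export
plot.mtrrp_curve <- function(x, ...) {
  plot(x$thresholds, x$rates, type = "b", pch = 16,
       xlab = "recurrence threshold (normalized units)",
       ylab = "recurrence rate", ...)
  invisible(x)
}

# Index of the plateau onset: the smallest threshold whose RR has reached
# `fraction` of the final RR. Everything strictly before it is the
# pre-plateau (rising) segment.
plateau_index <- function(curve, fraction = 0.95) {
  target <- fraction * curve$rates[length(curve$rates)]
  idx <- which(curve$rates >= target)
  if (!length(idx)) length(curve$rates) else idx[1]
}

#' Recurrence Rate Gradient
#'
#' Slope of the initial, rising segment of an MTRRP curve: the
#' ordinary-least-squares slope of RR against threshold over
#' `[eps_min, cutoff]`. A steep gradient means nearby states proliferate
#' quickly as the threshold grows - the signature of noise-like local
#' randomness. The cutoff is either a uniform maximum threshold
#' (`fit_strategy = "uniform_max"`) or the per-series recurrence-rate
#' stabilization point (`"per_series_plateau"`, default: the smallest
#' threshold whose RR reaches `plateau_fraction` of the final RR).
#'
#' @param curve An `mtrrp_curve`.
#' @param fit_strategy "per_series_plateau" (default) or "uniform_max".
#' @param plateau_fraction Plateau definition (default 0.95).
#' @param uniform_max_eps Fit cutoff when `fit_strategy = "uniform_max"`.
#' @return Slope in units of recurrence rate per unit threshold.
#' @export
recurrence_rate_gradient <- function(curve,
                                     fit_strategy = c("per_series_plateau",
                                                      "uniform_max"),
                                     plateau_fraction = 0.95,
                                     uniform_max_eps = NULL) {
  stopifnot(inherits(curve, "mtrrp_curve"))
  fit_strategy <- match.arg(fit_strategy)
  cutoff <- if (fit_strategy == "uniform_max") {
    if (is.null(uniform_max_eps)) {
      stop("`uniform_max_eps` is required for fit_strategy = 'uniform_max'",
           call. = FALSE)
    }
    uniform_max_eps
  } else {
    curve$thresholds[plateau_index(curve, plateau_fraction)]
  }
  sel <- curve$thresholds <= cutoff + 1e-12
  if (sum(sel) < 3L) {
    stop(sprintf(
      "fewer than 3 curve points at or below the fit cutoff %.3g", cutoff),
      call. = FALSE)
  }
  eps <- curve$thresholds[sel]
  rr <- curve$rates[sel]
  sum((eps - mean(eps)) * (rr - mean(rr))) / sum((eps - mean(eps))^2)
}

#' Recurrence Hurst
#'
#' Hurst-like exponent read off an MTRRP curve through the model
#' RR(eps) = alpha * (1 - RH * log eps). Each pre-plateau threshold gives
#' a per-threshold estimate h_k = (1 - RR_k / alpha) / log(eps_k); the
#' estimates are aggregated by the median (robust to the blow-up as
#' eps -> 1, where log eps -> 0) or the mean. Thresholds at eps = 1
#' (zero log) and at RR = 1 are skipped and recorded in the diagnostics.
#'
#' Note the sign convention: for normalized data log eps < 0 below
#' eps = 1, so h_k is negative whenever RR < alpha. Values are reported
#' exactly as computed; what carries information is how they order across
#' signals of different persistence.
#'
#' @param curve An `mtrrp_curve`.
#' @param aggregate "median" (default) or "mean".
#' @param plateau_fraction Pre-plateau definition (default 0.95). If fewer
#'   than 3 pre-plateau points exist, all usable points are aggregated
#'   instead.
#' @param alpha Model constant; defaults to the one stored in the curve.
#' @return The aggregated Recurrence Hurst; attribute `n_used` gives the
#'   number of thresholds aggregated and `skipped` those excluded.
#' @export
recurrence_hurst <- function(curve, aggregate = c("median", "mean"),
                             plateau_fraction = 0.95, alpha = NULL) {
  stopifnot(inherits(curve, "mtrrp_curve"))
  aggregate <- match.arg(aggregate)
  if (is.null(alpha)) alpha <- curve$alpha
  eps <- curve$thresholds
  rr <- curve$rates
  # eps within rounding distance of 1 must go too: log(eps) -> 0 makes the
  # per-threshold estimate pure cancellation noise
  usable <- eps > 0 & eps < 1 - 1e-9 & rr < 1
  if (!any(usable)) {
    stop("degenerate curve: no threshold with eps < 1 and RR < 1",
         call. = FALSE)
  }
  pre <- seq_along(eps) < plateau_index(curve, plateau_fraction)
  sel <- usable & pre
  if (sum(sel) < 3L) sel <- usable
  h <- (1 - rr[sel] / alpha) / log(eps[sel])
  out <- if (aggregate == "median") stats::median(h) else mean(h)
  attr(out, "n_used") <- sum(sel)
  attr(out, "skipped") <- sum(!usable)
  out
}

#' Recurrence Complexity
#'
#' Product of the Recurrence Rate Gradient and the Recurrence Hurst: a
#' joint index of local randomness (the gradient) and long-range
#' persistence (the Hurst term).
#'
#' @param rrg Recurrence Rate Gradient.
#' @param rh Recurrence Hurst.
#' @return `rrg * rh`.
#' @export
recurrence_complexity <- function(rrg, rh) {
  if (!is.finite(rrg) || !is.finite(rh)) {
    stop("both inputs must be finite", call. = FALSE)
  }
  as.numeric(rrg) * as.numeric(rh)
}

#' All three MTRRP metrics of a series
#'
#' Convenience wrapper: builds the MTRRP curve and returns the Recurrence
#' Rate Gradient, Recurrence Hurst, and Recurrence Complexity together.
#'
#' @inheritParams mtrrp_curve
#' @param ... Passed to [mtrrp_curve()].
#' @return Object of class `mtrrp_metrics`: list with `rrg`, `rh`, `rc`
#'   (rc = rrg * rh exactly) and the underlying `curve`.
#' @export
mtrrp_metrics <- function(series, ...) {
  curve <- mtrrp_curve(series, ...)
  rrg <- recurrence_rate_gradient(curve)
  rh <- as.numeric(recurrence_hurst(curve))
  structure(list(rrg = rrg, rh = rh, rc = rrg * rh, curve = curve),
            class = "mtrrp_metrics")
}

#' @export
print.mtrrp_metrics <- function(x, ...) {
  cat(sprintf("MTRRP metrics: RRG = %.4f, RH = %.4f, RC = %.4f\n",
              x$rrg, x$rh, x$rc))
  invisible(x)
}

#' Fit the recurrence-rate model to an MTRRP curve
#'
#' Jointly estimates the model constant alpha and the Recurrence Hurst by
#' nonlinear least squares of RR(eps) = alpha * (1 - RH * log eps) over the
#' pre-plateau points of a curve. Used to check that classical Brownian
#' motion yields alpha near 0.5, the value for which the model and the
#' Recurrence Hurst inverse are calibrated.
#'
#' @param curve An `mtrrp_curve`.
#' @param plateau_fraction Pre-plateau definition (default 0.95).
#' @return List with `alpha`, `rh`, `n_points`, and the `nls` fit object.
#' @export
fit_rr_model <- function(curve, plateau_fraction = 0.95) {
  stopifnot(inherits(curve, "mtrrp_curve"))
  below_one <- curve$thresholds < 1 - 1e-9
  pre <- seq_along(curve$thresholds) < plateau_index(curve, plateau_fraction)
  sel <- pre & below_one
  if (sum(sel) < 3L) sel <- below_one
  df <- data.frame(eps = curve$thresholds[sel], rr = curve$rates[sel])
  if (nrow(df) < 3L) stop("too few points to fit the model", call. = FALSE)
  # scaleOffset keeps the relative-offset test meaningful when the curve
  # follows the model (near) exactly
  fit <- stats::nls(rr ~ a * (1 - h * log(eps)), data = df,
                    start = list(a = 0.5, h = -0.3),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE,
                                                 scaleOffset = 1))
  cf <- stats::coef(fit)
  list(alpha = unname(cf["a"]), rh = unname(cf["h"]),
       n_points = nrow(df), fit = fit)
}
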