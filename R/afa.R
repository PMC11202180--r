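#' Cumulative integration of a series
#'
#' Forms the integrated profile X(i) = sum_{j <= i} x(j), turning an
#' increment series (fractional-Gaussian-noise-like) into a path
#' (fractional-Brownian-motion-like). First differences of the output
#' recover the input.
#'
#' @param series Numeric vector.
#' @return Numeric vector of the same length.
#' @export
afa_integrate <- function(series) {
  check_series(series, min_len = 1L)
  cumsum(series)
}

#' Default AFA window ladder
#'
#' Odd window sizes 2^k + 1 growing dyadically from 5 up to n/8.
#'
#' @param n Series length.
#' @return Integer vector of odd window sizes.
#' @export
afa_windows <- function(n) {
  w <- 2L^(2:30) + 1L
  w <- w[w <= n / 8]
  if (length(w) < 3L) {
    stop(sprintf("series of length %d is too short for an AFA ladder", n),
         call. = FALSE)
  }
  w
}

# Adaptive trend of `u` at one odd window size W = 2h + 1: overlapping
# windows with step h, a polynomial of order `order` fitted in each, and
# neighbouring fits blended with triangular center-peaked weights (1 at the
# window center, decaying linearly to 0 at the edges), which sum to 1 in
# every regular overlap. Boundary half-windows take their single fit.
afa_trend <- function(u, w, order = 1L) {
  n <- length(u)
  h <- (w - 1L) %/% 2L
  if (w %% 2L == 0L || w < 3L) stop("window size must be odd and >= 3",
                                    call. = FALSE)
  if (w > n) stop("window exceeds series length", call. = FALSE)
  starts <- seq.int(1L, n - w + 1L, by = h)
  if (starts[length(starts)] < n - w + 1L) starts <- c(starts, n - w + 1L)
  k <- length(starts)
  idx <- outer(starts, 0:(w - 1L), "+")
  y <- matrix(u[idx], nrow = k)
  tt <- 0:(w - 1L)
  vand <- outer(tt, 0:order, "^")
  hat <- vand %*% solve(crossprod(vand), t(vand)) # W x W projection
  fits <- y %*% t(hat)
  wt <- 1 - abs(tt - h) / h # triangular, 0 at edges, 1 at center
  wt_first <- wt
  wt_first[tt <= h] <- 1 # no left partner for the first window
  wt_last <- wt
  wt_last[tt >= h] <- 1 # no right partner for the last window
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_len(k)) {
    wj <- if (j == 1L) wt_first else if (j == k) wt_last else wt
    span <- idx[j, ]
    num[span] <- num[span] + wj * fits[j, ]
    den[span] <- den[span] + wj
  }
  num / den
}

#' Adaptive fractal analysis Hurst estimate
#'
#' Estimates the Hurst exponent of a series by adaptive fractal analysis:
#' the integrated profile u is detrended at each window size W by an
#' adaptively stitched local polynomial trend v (overlapping windows,
#' triangular weights peaked at the window center), the residual
#' fluctuation F(W) = rms(u - v) is recorded, and H is the slope of the
#' least-squares line of log2 F(W) against log2 W.
#'
#' Whether the input is an increment series (to be integrated first) or an
#' already-integrated path must be stated explicitly via
#' `input_is_increments`: confusing the two shifts the estimate by a whole
#' unit of H.
#'
#' @param series Numeric vector; length must be at least 4 x the largest
#'   window.
#' @param window_sizes Odd window sizes (default: dyadic ladder from 5 to
#'   n/8, see [afa_windows()]).
#' @param detrend_order Polynomial order of the local fits (default 1,
#'   linear).
#' @param input_is_increments If `TRUE`, the series is integrated before
#'   analysis (default `FALSE`: the input is already a path/profile).
#' @return Object of class `afa_fit`: list with `hurst`, `r_squared`,
#'   `window_sizes`, `fluctuations`, `detrend_order`,
#'   `input_is_increments`.
#' @export
afa_fit <- function(series, window_sizes = NULL, detrend_order = 1L,
                    input_is_increments = FALSE) {
  check_series(series, min_len = 64L)
  u <- if (input_is_increments) afa_integrate(series) else as.numeric(series)
  n <- length(u)
  if (is.null(window_sizes)) window_sizes <- afa_windows(n)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (any(window_sizes %% 2L == 0L) || any(window_sizes < 3L)) {
    stop("window sizes must be odd and >= 3", call. = FALSE)
  }
  if (max(window_sizes) > n / 4) {
    stop(sprintf("largest window %d exceeds n/4 = %g", max(window_sizes),
                 n / 4), call. = FALSE)
  }
  fl <- vapply(window_sizes, function(w) {
    v <- afa_trend(u, w, order = detrend_order)
    sqrt(mean((u - v)^2))
  }, numeric(1))
  scale <- stats::sd(u)
  if (any(fl <= 1e-12 * max(scale, 1))) {
    stop(paste0("degenerate fit: residuals vanish (series is exactly ",
                "polynomial at the detrending order)"), call. = FALSE)
  }
  lw <- log2(window_sizes)
  lf <- log2(fl)
  fit <- stats::lm.fit(cbind(1, lw), lf)
  hurst <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((lf - mean(lf))^2)
  structure(list(hurst = hurst, r_squared = r2,
                 window_sizes = window_sizes, fluctuations = fl,
                 detrend_order = as.integer(detrend_order),
                 input_is_increments = input_is_increments),
            class = "afa_fit")
}

#' @export
print.afa_fit <- function(x, ...) {
  cat(sprintf("AFA fit: H = %.3f (R^2 = %.3f) over %d windows [%d, %d]\n",
              x$hurst, x$r_squared, length(x$window_sizes),
              min(x$window_sizes), max(x$window_sizes)))
  invisible(x)
}
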