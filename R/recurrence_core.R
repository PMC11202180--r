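#' Time-delay embedding
#'
#' Reconstructs phase-space vectors X_i = (x_i, x_{i+tau}, ...,
#' x_{i+(m-1)tau}) from a scalar series. The trajectory has
#' n - (m-1)*tau points.
#'
#' @param series Numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1).
#' @return Numeric matrix with one phase-space point per row and `m`
#'   columns; attribute `source_length` records the original n.
#' @export
embed_series <- function(series, m, tau) {
  check_series(series)
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("`m` and `tau` must be >= 1", call. = FALSE)
  n <- length(series)
  n_vec <- n - (m - 1L) * tau
  if (n_vec < 1L) {
    stop(sprintf(
      "series too short to embed: n = %d but m = %d, tau = %d need n > %d",
      n, m, tau, (m - 1L) * tau), call. = FALSE)
  }
  out <- matrix(0, nrow = n_vec, ncol = m)
  for (k in seq_len(m)) {
    out[, k] <- series[seq.int((k - 1L) * tau + 1L, length.out = n_vec)]
  }
  attr(out, "source_length") <- n
  out
}

#' Select embedding parameters
#'
#' Chooses the delay tau as the first lag at which the autocorrelation
#' function drops below 1/e, or the first local minimum of a histogram
#' estimate of the time-delayed mutual information; and the embedding
#' dimension m as the smallest dimension whose false-nearest-neighbour
#' fraction falls below `fnn_threshold` (capped at `m_max`).
#'
#' @param series Numeric vector of length >= 256.
#' @param tau_method "autocorrelation" (default) or "mutual_information".
#' @param fnn_threshold Acceptable false-neighbour fraction (default 0.01).
#' @param m_max Largest dimension tried (default 10).
#' @param fnn_points At most this many trajectory points enter the O(N^2)
#'   neighbour search (evenly subsampled; default 500).
#' @return List with elements `m` and `tau`.
#' @export
select_embedding_params <- function(series,
                                    tau_method = c("autocorrelation",
                                                   "mutual_information"),
                                    fnn_threshold = 0.01,
                                    m_max = 10L,
                                    fnn_points = 500L) {
  check_series(series, min_len = 256L)
  tau_method <- match.arg(tau_method)
  tau <- select_delay(series, tau_method)
  m <- select_dimension_fnn(series, tau, fnn_threshold, m_max, fnn_points)
  list(m = m, tau = tau)
}

select_delay <- function(series, tau_method) {
  n <- length(series)
  max_lag <- floor(n / 4)
  if (tau_method == "autocorrelation") {
    # grow the lag window geometrically: most signals cross 1/e early and
    # a full-length ACF on a long recording would dominate the runtime
    lag_hi <- min(max_lag, 64L)
    repeat {
      ac <- stats::acf(series, lag.max = lag_hi, plot = FALSE,
                       demean = TRUE)$acf[-1]
      hit <- which(ac < exp(-1))
      if (length(hit)) return(hit[1])
      if (lag_hi >= max_lag) break
      lag_hi <- min(max_lag, lag_hi * 4L)
    }
    stop(sprintf(
      "no lag within n/4 = %d where autocorrelation drops below 1/e",
      max_lag), call. = FALSE)
  } else {
    mi <- vapply(seq_len(max_lag), function(l) {
      lagged_mutual_information(series, l)
    }, numeric(1))
    # first local minimum
    for (l in seq_len(max_lag - 1L)) {
      if (l == 1L) next
      if (mi[l] < mi[l - 1L] && mi[l] <= mi[l + 1L]) return(l)
    }
    stop(sprintf("no local minimum of mutual information within n/4 = %d",
                 max_lag), call. = FALSE)
  }
}

lagged_mutual_information <- function(x, lag, bins = 16L) {
  a <- x[seq_len(length(x) - lag)]
  b <- x[(lag + 1):length(x)]
  br <- seq(min(x), max(x), length.out = bins + 1L)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(ia, ib) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

select_dimension_fnn <- function(series, tau, fnn_threshold, m_max,
                                 fnn_points) {
  rtol <- 10 # standard Kennel ratio test
  for (m in seq_len(m_max)) {
    n_vec <- length(series) - m * tau # points that embed in both m and m+1
    if (n_vec < 10L) return(max(1L, m - 1L))
    emb <- embed_series(series, m + 1L, tau)
    keep <- seq_len(n_vec)
    if (n_vec > fnn_points) {
      keep <- unique(round(seq(1L, n_vec, length.out = fnn_points)))
    }
    low <- emb[keep, seq_len(m), drop = FALSE]
    nxt <- emb[keep, m + 1L]
    d2 <- as.matrix(stats::dist(low))^2
    diag(d2) <- Inf
    nn <- apply(d2, 1L, which.min)
    dnn <- sqrt(d2[cbind(seq_along(nn), nn)])
    # floor the neighbour distance at a fraction of the signal scale:
    # exactly recurring states (periodic signals) otherwise produce 0/0
    # ratios that are pure rounding noise
    dnn <- pmax(dnn, 1e-8 * stats::sd(series))
    false_frac <- mean(abs(nxt - nxt[nn]) / dnn > rtol)
    if (false_frac < fnn_threshold) return(m)
  }
  m_max
}

#' Recurrence matrix
#'
#' Binary matrix R[i, j] = 1 when the phase-space points i and j lie within
#' distance `epsilon` of each other and |i - j| >= `theiler`. With
#' `theiler = 0` the main diagonal (the line of identity) is all ones.
#'
#' @param ps Phase-space matrix from [embed_series()] (a plain numeric
#'   vector is treated as a 1-dimensional embedding).
#' @param epsilon Recurrence threshold (>= 0), in the units of the data.
#' @param norm "euclidean" (default) or "chebyshev"; identical for
#'   1-dimensional embeddings.
#' @param theiler Exclusion half-width around the diagonal (default 0, so
#'   every cell is counted).
#' @param max_n Guard: refuse to materialize matrices larger than
#'   `max_n` x `max_n` (default 5000); use [mtrrp_curve()] /
#'   [recurrence_rates_at()] for threshold sweeps on long series.
#' @return Object of class `recurrence_matrix`: the 0/1 integer matrix with
#'   attributes `epsilon`, `norm`, `theiler`.
#' @export
recurrence_matrix <- function(ps, epsilon, norm = c("euclidean", "chebyshev"),
                              theiler = 0L, max_n = 5000L) {
  norm <- match.arg(norm)
  if (is.null(dim(ps))) ps <- matrix(as.numeric(ps), ncol = 1L)
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  n <- nrow(ps)
  if (n > max_n) {
    stop(sprintf(paste0(
      "trajectory has %d points; matrices above %d x %d are not ",
      "materialized - use recurrence_rates_at() instead"), n, max_n, max_n),
      call. = FALSE)
  }
  d <- pairwise_distances(ps, norm)
  rm <- matrix(0L, n, n)
  rm[d <= epsilon] <- 1L
  if (theiler > 0L) {
    band <- abs(outer(seq_len(n), seq_len(n), "-")) < theiler
    rm[band] <- 0L
  }
  structure(rm, epsilon = epsilon, norm = norm, theiler = as.integer(theiler),
            class = c("recurrence_matrix", "matrix"))
}

pairwise_distances <- function(ps, norm) {
  if (norm == "euclidean") {
    sq <- rowSums(ps^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(ps)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    n <- nrow(ps)
    d <- matrix(0, n, n)
    for (c in seq_len(ncol(ps))) {
      d <- pmax(d, abs(outer(ps[, c], ps[, c], "-")))
    }
    d
  }
}

#' Recurrence rate
#'
#' Fraction of recurrence points among all counted cells of a recurrence
#' matrix. Cells inside the Theiler band are excluded from both numerator
#' and denominator.
#'
#' @param rm A `recurrence_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
recurrence_rate <- function(rm) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  n <- nrow(rm)
  theiler <- attr(rm, "theiler")
  counted <- n^2 - theiler_band_cells(n, theiler)
  if (counted <= 0) {
    stop("Theiler window excludes every cell; nothing to count",
         call. = FALSE)
  }
  sum(rm) / counted
}

theiler_band_cells <- function(n, theiler) {
  if (theiler <= 0L) return(0)
  offs <- seq_len(theiler) - 1L # |i - j| in 0 .. theiler-1
  n + 2 * sum(pmax(n - offs[-1], 0))
}

#' Recurrence rates over a threshold ladder
#'
#' Computes RR(eps) for every threshold of a sorted ladder in one pass over
#' the pairwise distances, without materializing any recurrence matrix.
#' This is the O(n^2)-time, O(1)-memory backend used for long series.
#'
#' @inheritParams recurrence_matrix
#' @param epsilons Increasing numeric vector of thresholds.
#' @return Numeric vector of recurrence rates, one per threshold,
#'   non-decreasing.
#' @export
recurrence_rates_at <- function(ps, epsilons,
                                norm = c("euclidean", "chebyshev"),
                                theiler = 0L) {
  norm <- match.arg(norm)
  if (is.null(dim(ps))) ps <- matrix(as.numeric(ps), ncol = 1L)
  if (is.unsorted(epsilons, strictly = FALSE)) {
    stop("`epsilons` must be sorted increasing", call. = FALSE)
  }
  if (any(epsilons < 0)) stop("thresholds must be >= 0", call. = FALSE)
  n <- nrow(ps)
  theiler <- as.integer(theiler)
  counted <- n^2 - theiler_band_cells(n, theiler)
  if (counted <= 0) {
    stop("Theiler window excludes every cell; nothing to count",
         call. = FALSE)
  }
  pair_counts <- rr_count_pairs(ps, as.numeric(epsilons), theiler,
                                norm == "chebyshev")
  diag_cells <- if (theiler <= 0L) n else 0L
  (2 * pair_counts + diag_cells) / counted
}
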