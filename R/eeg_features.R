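#' Conventional EEG frequency bands
#'
#' Band edges in Hz: Delta 0.5-4, Theta 4-8, Alpha 8-13, Beta 13-30,
#' Gamma 30-45. The optional FullBand (0.5-45 Hz) spans the usual clinical
#' pre-filtering envelope and is off by default so the standard feature
#' table keeps its channels x 5 bands x 3 metrics layout.
#'
#' @param include_full Append the FullBand row (default `FALSE`).
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function(include_full = FALSE) {
  b <- data.frame(
    name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    low = c(0.5, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
  if (include_full) {
    b <- rbind(b, data.frame(name = "FullBand", low = 0.5, high = 45))
  }
  b
}

#' Zero-phase Butterworth band-pass of a recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, so no band-dependent group delay) to every channel of a
#' recording. Length is preserved.
#'
#' @param recording A recording as produced by [generate_synthetic_eeg()]
#'   or [read_eeg_csv()]: list with `data` (samples x channels matrix) and
#'   `sampling_rate`.
#' @param low,high Band edges in Hz; `high` must stay below the Nyquist
#'   frequency.
#' @param order Filter order (default 4).
#' @return The recording with filtered `data`.
#' @export
bandpass_recording <- function(recording, low, high, order = 4L) {
  fs <- recording$sampling_rate
  if (is.null(fs) || !is.finite(fs)) {
    stop("recording has no sampling rate", call. = FALSE)
  }
  if (low <= 0 || high <= low) stop("need 0 < low < high", call. = FALSE)
  if (high >= fs / 2) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 high, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  out$data <- apply(recording$data, 2L, function(ch) {
    signal::filtfilt(bf, ch)
  })
  colnames(out$data) <- colnames(recording$data)
  out
}

#' Read a multi-channel recording from CSV
#'
#' Loads one recording stored as plain CSV with one column per channel
#' (header row = channel names).
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id,group Optional metadata.
#' @return Recording list compatible with [bandpass_recording()] and
#'   [extract_features()].
#' @export
read_eeg_csv <- function(path, sampling_rate, subject_id = basename(path),
                         group = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(subject_id = subject_id, group = group,
       sampling_rate = sampling_rate,
       data = as.matrix(df))
}

#' MTRRP feature table of an EEG cohort
#'
#' For every subject, channel and frequency band: band-pass filter the
#' channel, compute its MTRRP curve (epoched for long recordings), and
#' store the three derived metrics. With the 19-channel montage and the
#' five conventional bands this yields the 285-column feature layout
#' (19 channels x 5 bands x 3 metrics).
#'
#' @param recordings List of recordings sharing montage and sampling rate.
#' @param bands Band table from [eeg_bands()].
#' @param m,tau,eps_min,q,epoch_length,alpha MTRRP parameters, see
#'   [mtrrp_curve()]. With the default `tau = NULL` the delay is selected
#'   per channel and band by the autocorrelation criterion.
#' @param max_seconds Use at most this many seconds from the start of each
#'   recording (default 300, the conventional 5-minute resting segment);
#'   `Inf` uses everything.
#' @param filter_order Butterworth order (default 4).
#' @return Object of class `mtrrp_features`: data frame with `subject_id`,
#'   `group`, then one column per (channel, band, metric) named
#'   `channel.band.metric` with metric in RRG, RH, RC.
#' @export
extract_features <- function(recordings, bands = eeg_bands(),
                             m = 2L, tau = NULL, eps_min = 0.1, q = 0.3,
                             epoch_length = 2000L, alpha = 0.5,
                             max_seconds = 300, filter_order = 4L) {
  stopifnot(length(recordings) >= 1L)
  channels <- colnames(recordings[[1]]$data)
  fs <- recordings[[1]]$sampling_rate
  for (rec in recordings) {
    if (!identical(rec$sampling_rate, fs)) {
      stop("recordings disagree on sampling rate", call. = FALSE)
    }
    missing_ch <- setdiff(channels, colnames(rec$data))
    if (length(missing_ch)) {
      stop(sprintf("subject %s is missing channel(s): %s",
                   rec$subject_id, paste(missing_ch, collapse = ", ")),
           call. = FALSE)
    }
  }
  metrics <- c("RRG", "RH", "RC")
  feat_names <- as.vector(vapply(channels, function(ch) {
    as.vector(vapply(bands$name, function(b) paste(ch, b, metrics, sep = "."),
                     character(3)))
  }, character(3 * nrow(bands))))
  rows <- lapply(recordings, function(rec) {
    n_keep <- min(nrow(rec$data), ceiling(max_seconds * fs))
    rec$data <- rec$data[seq_len(n_keep), channels, drop = FALSE]
    vals <- numeric(length(feat_names))
    i <- 0L
    for (ch in channels) {
      for (bi in seq_len(nrow(bands))) {
        filt <- bandpass_recording(
          list(sampling_rate = fs,
               data = rec$data[, ch, drop = FALSE]),
          low = bands$low[bi], high = bands$high[bi], order = filter_order)
        mm <- mtrrp_metrics(as.numeric(filt$data), m = m, tau = tau,
                            eps_min = eps_min, q = q,
                            epoch_length = epoch_length, alpha = alpha)
        vals[i + 1:3] <- c(mm$rrg, mm$rh, mm$rc)
        i <- i + 3L
      }
    }
    vals
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- feat_names
  out <- cbind(
    data.frame(
      subject_id = vapply(recordings, `[[`, character(1), "subject_id"),
      group = vapply(recordings, function(r) {
        as.character(r$group %||% NA_character_)
      }, character(1)),
      stringsAsFactors = FALSE
    ),
    tab
  )
  rownames(out) <- NULL
  structure(out, feature_cols = feat_names,
            class = c("mtrrp_features", "data.frame"))
}

#' Feature matrix of a feature table
#' @param ft An `mtrrp_features` table.
#' @return Numeric matrix (subjects x features).
#' @export
feature_matrix <- function(ft) {
  stopifnot(inherits(ft, "mtrrp_features"))
  as.matrix(ft[, attr(ft, "feature_cols"), drop = FALSE])
}

#' Group labels of a feature table
#' @param ft An `mtrrp_features` table.
#' @return Factor of group labels, levels in order of first appearance.
#' @export
feature_labels <- function(ft) {
  stopifnot(inherits(ft, "mtrrp_features"))
  factor(ft$group, levels = unique(ft$group))
}
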