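#' One-way ANOVA over features or regions
#'
#' One-way ANOVA of each feature (or each region aggregate) across groups,
#' with Bonferroni correction over the whole comparison family and the
#' partial eta squared effect size. Pairwise post-hoc t comparisons,
#' Bonferroni-adjusted, are attached as an attribute.
#'
#' @param x Numeric matrix (subjects x features) or an `mtrrp_features`
#'   table.
#' @param groups Factor of group membership (taken from the table when `x`
#'   is one).
#' @param grouping Optional named list mapping a region name to the feature
#'   columns averaged into that region before testing; `NULL` tests every
#'   column separately.
#' @return Data frame with columns `feature`, `F`, `df1`, `df2`, `p_raw`,
#'   `p_adjusted`, `partial_eta_sq`; attribute `posthoc` holds the pairwise
#'   p-value matrices.
#' @export
groupwise_anova <- function(x, groups = NULL, grouping = NULL) {
  if (inherits(x, "mtrrp_features")) {
    if (is.null(groups)) groups <- feature_labels(x)
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  if (!is.null(grouping)) {
    x <- vapply(grouping, function(cols) {
      rowMeans(x[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    colnames(x) <- names(grouping)
  }
  feats <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    tab <- stats::anova(stats::aov(v ~ groups))
    f_val <- tab$`F value`[1]
    df1 <- tab$Df[1]
    df2 <- tab$Df[2]
    peta <- f_val * df1 / (f_val * df1 + df2)
    ph <- stats::pairwise.t.test(v, groups, p.adjust.method = "bonferroni",
                                 pool.sd = FALSE)$p.value
    list(row = data.frame(feature = feats[j], F = f_val, df1 = df1,
                          df2 = df2, p_raw = tab$`Pr(>F)`[1],
                          partial_eta_sq = peta,
                          stringsAsFactors = FALSE),
         posthoc = ph)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out <- out[, c("feature", "F", "df1", "df2", "p_raw", "p_adjusted",
                 "partial_eta_sq")]
  rownames(out) <- NULL
  attr(out, "posthoc") <- stats::setNames(lapply(res, `[[`, "posthoc"),
                                          out$feature)
  out
}

# 0/1 encoding of a two-class label vector for Pearson ranking.
encode_labels01 <- function(labels) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop("labels must have exactly 2 classes",
                             call. = FALSE)
  as.numeric(f) - 1
}

#' Pearson-correlation feature ranking
#'
#' Ranks features by the absolute Pearson correlation between each feature
#' and the (0/1-encoded) class labels, returning the top `k` column
#' indices. Zero-variance features get |r| = 0 (with a warning). Ties are
#' broken by the earlier column index, so the ranking is stable.
#'
#' @param x Numeric matrix (rows = the subjects the ranking may see, i.e.
#'   training rows only inside a cross-validation fold).
#' @param labels Two-class labels for those rows.
#' @param k Number of features to keep (default 50).
#' @return Integer vector of `k` column indices, best first; attribute
#'   `abs_r` carries their |r| values.
#' @export
select_features_pearson <- function(x, labels, k = 50L) {
  x <- as.matrix(x)
  y <- encode_labels01(labels)
  if (k > ncol(x)) {
    stop(sprintf("k = %d exceeds the %d available features", k, ncol(x)),
         call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd)
  r <- rep(0, ncol(x))
  ok <- sds > 0
  if (any(!ok)) warning("zero-variance feature(s) ranked with |r| = 0")
  r[ok] <- as.numeric(stats::cor(x[, ok, drop = FALSE], y))
  ord <- order(-abs(r), seq_along(r))
  idx <- ord[seq_len(k)]
  attr(idx, "abs_r") <- abs(r)[idx]
  idx
}

#' SVM with leave-one-out cross-validation
#'
#' The classification protocol: for each held-out subject, features are
#' ranked by Pearson correlation with the labels on the remaining n - 1
#' subjects, the top `k` are kept, training rows are standardized, an SVM
#' is fitted and the held-out subject predicted. Feature selection and
#' standardization happen inside every fold, so no information leaks from
#' the test subject (a `selection = "global"` variant that selects once on
#' all rows is available for comparison).
#'
#' @param x Numeric matrix (subjects x features) or `mtrrp_features` table.
#' @param labels Two-class labels (taken from the table when `x` is one).
#' @param k Number of features selected per fold (default 50, capped at
#'   the number of available features).
#' @param kernel SVM kernel (default "linear").
#' @param cost SVM cost parameter C (default 1).
#' @param positive Label treated as the positive class for recall /
#'   specificity (default: the second factor level).
#' @param selection "per_fold" (default, leakage-safe) or "global".
#' @param class_weights "none" (default) or "balanced".
#' @param seed Integer seed (the protocol is deterministic given data and
#'   seed).
#' @return Object of class `classification_report`: list with `accuracy`,
#'   `recall`, `specificity`, `confusion` (TP, TN, FP, FN), `n`,
#'   `predictions`, `selected_features` (per fold), `config`.
#' @export
svm_loocv <- function(x, labels = NULL, k = 50L, kernel = "linear",
                      cost = 1, positive = NULL,
                      selection = c("per_fold", "global"),
                      class_weights = c("none", "balanced"), seed = 1L) {
  if (inherits(x, "mtrrp_features")) {
    if (is.null(labels)) labels <- feature_labels(x)
    x <- feature_matrix(x)
  }
  selection <- match.arg(selection)
  class_weights <- match.arg(class_weights)
  x <- as.matrix(x)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("exactly two classes are required",
                             call. = FALSE)
  n <- nrow(x)
  if (n < 6L) stop("need at least 6 subjects for LOOCV", call. = FALSE)
  k <- min(as.integer(k), ncol(x))
  if (is.null(positive)) positive <- levels(y)[2]
  cw <- if (class_weights == "balanced") {
    tb <- table(y)
    stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  } else {
    NULL
  }
  global_idx <- if (selection == "global") {
    select_features_pearson(x, y, k)
  } else {
    NULL
  }
  preds <- character(n)
  selected <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      ytr <- y[tr]
      if (nlevels(droplevels(ytr)) < 2L) {
        stop("a class is absent from a training fold", call. = FALSE)
      }
      idx <- if (selection == "global") {
        global_idx
      } else {
        select_features_pearson(x[tr, , drop = FALSE], ytr, k)
      }
      selected[[i]] <- idx
      xtr <- x[tr, idx, drop = FALSE]
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
      xte <- (x[i, idx] - mu) / sdv
      fit <- e1071::svm(xtr, ytr, kernel = kernel, cost = cost,
                        scale = FALSE, class.weights = cw)
      preds[i] <- as.character(stats::predict(
        fit, matrix(xte, nrow = 1L)))
    }
  })
  is_pos <- y == positive
  pred_pos <- preds == positive
  tp <- sum(is_pos & pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  fp <- sum(!is_pos & pred_pos)
  fn <- sum(is_pos & !pred_pos)
  structure(list(
    accuracy = (tp + tn) / n,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    n = n,
    predictions = stats::setNames(preds, rownames(x)),
    selected_features = selected,
    config = list(k = k, kernel = kernel, cost = cost, positive = positive,
                  selection = selection, class_weights = class_weights,
                  seed = seed)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "SVM-LOOCV (n = %d, k = %d, %s kernel): accuracy %.1f%%, recall %.1f%%, specificity %.1f%%\n",
    x$n, x$config$k, x$config$kernel, 100 * x$accuracy, 100 * x$recall,
    100 * x$specificity))
  invisible(x)
}

#' Label-permutation test of the classification protocol
#'
#' Builds an empirical null for the LOOCV accuracy by shuffling the group
#' labels and re-running the complete protocol on each shuffle - including
#' the per-fold Pearson feature re-selection, so the null reflects every
#' opportunity for overfitting the real run had. The p-value uses the
#' standard +1 correction: p = (1 + #{null >= observed}) / (1 + n_perm),
#' hence never below 1/(n_perm + 1).
#'
#' @inheritParams svm_loocv
#' @param n_perm Number of label shuffles (default 200).
#' @param ... Passed on to [svm_loocv()].
#' @return Object of class `permutation_result`: list with `p_value`,
#'   `observed_accuracy`, `null_accuracies` (length `n_perm`), `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(x, labels = NULL, n_perm = 200L, k = 50L,
                             seed = 1L, ...) {
  if (inherits(x, "mtrrp_features")) {
    if (is.null(labels)) labels <- feature_labels(x)
    x <- feature_matrix(x)
  }
  if (n_perm < 20L) {
    warning("n_perm < 20 gives unstable permutation p-values")
  }
  y <- droplevels(as.factor(labels))
  observed <- svm_loocv(x, y, k = k, seed = seed, ...)$accuracy
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yb <- sample(y)
      svm_loocv(x, yb, k = k, seed = child_seed(seed, b), ...)$accuracy
    }, numeric(1))
  })
  p <- (1 + sum(null_acc >= observed)) / (1 + n_perm)
  structure(list(p_value = p, observed_accuracy = observed,
                 null_accuracies = null_acc, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed accuracy %.1f%%, null mean %.1f%%, p = %.4g (%d shuffles)\n",
    100 * x$observed_accuracy, 100 * mean(x$null_accuracies), x$p_value,
    x$n_perm))
  invisible(x)
}
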