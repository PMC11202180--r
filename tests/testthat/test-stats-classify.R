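test_that("one-way ANOVA matches a from-scratch sum-of-squares oracle", {
  set.seed(31)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  v <- c(1.2, 0.8, 1.5, 1.1, 2.4, 2.0, 2.7, 2.2, 0.3, 0.6, 0.1, 0.5)
  res <- groupwise_anova(matrix(v, ncol = 1), g)
  # independent decomposition
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F, f_oracle, tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 9)
  expect_equal(res$p_raw, stats::pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$partial_eta_sq, ssb / (ssb + ssw), tolerance = 1e-9)
})

test_that("identical groups give a null F and Bonferroni caps at one", {
  v <- rep(c(1, 2, 3, 4), 2)
  g <- factor(rep(c("x", "y"), each = 4))
  res <- groupwise_anova(matrix(v, ncol = 1), g)
  expect_equal(res$F, 0)
  expect_equal(res$p_raw, 1)
  set.seed(11)
  x <- matrix(rnorm(8 * 30), nrow = 8)
  res30 <- groupwise_anova(x, g)
  expect_equal(res30$p_adjusted, pmin(1, res30$p_raw * 30))
  expect_equal(res30$partial_eta_sq,
               res30$F * res30$df1 / (res30$F * res30$df1 + res30$df2))
  expect_error(groupwise_anova(x[1:5, ], factor(c(1, 1, 1, 1, 2))),
               "at least 2 subjects")
})

test_that("region grouping averages columns before testing", {
  set.seed(12)
  x <- matrix(rnorm(20 * 4), nrow = 20,
              dimnames = list(NULL, c("O1.RC", "O2.RC", "F3.RC", "F4.RC")))
  g <- factor(rep(c("p", "q"), each = 10))
  res <- groupwise_anova(x, g,
                         grouping = list(occipital = c("O1.RC", "O2.RC")))
  direct <- groupwise_anova(matrix(rowMeans(x[, 1:2]), ncol = 1), g)
  expect_equal(res$F, direct$F)
  expect_equal(res$feature, "occipital")
})

test_that("Pearson ranking is exact, stable under ties and guarded", {
  set.seed(21)
  y <- factor(rep(c("n", "p"), each = 10))
  x <- matrix(rnorm(20 * 6), nrow = 20)
  x[, 4] <- as.numeric(y) # feature equal to the labels
  idx <- select_features_pearson(x, y, k = 3)
  expect_equal(idx[1], 4L, ignore_attr = TRUE)
  expect_equal(attr(idx, "abs_r")[1], 1)
  xt <- cbind(x[, 4], x[, 4]) # exact tie: earlier column wins
  expect_equal(select_features_pearson(xt, y, k = 2)[1], 1L,
               ignore_attr = TRUE)
  xz <- x
  xz[, 2] <- 7 # zero variance
  expect_warning(idxz <- select_features_pearson(xz, y, k = 6),
                 "zero-variance")
  expect_equal(idxz[6], 2L, ignore_attr = TRUE) # ranked last with |r| = 0
  expect_error(select_features_pearson(x, y, k = 99), "exceeds")
})

test_that("noise features draw |r| from the small-sample null range", {
  set.seed(33)
  y <- factor(rep(c("n", "p"), each = 20))
  x <- matrix(rnorm(40 * 200), nrow = 40)
  idx <- select_features_pearson(x, y, k = 5)
  r <- attr(idx, "abs_r")
  expect_true(all(r > 0 & r < 0.7)) # extreme of 200 null draws at n = 40
})

test_that("separable clusters classify perfectly and identities hold", {
  set.seed(41)
  n <- 30
  y <- factor(rep(c("HC", "AD"), each = n / 2), levels = c("HC", "AD"))
  x <- matrix(rnorm(n * 10), nrow = n)
  x[y == "AD", ] <- x[y == "AD", ] + 10 # 10 sigma separation
  rep1 <- svm_loocv(x, y, k = 5, seed = 2)
  expect_equal(rep1$accuracy, 1.0)
  cf <- rep1$confusion
  expect_equal(sum(cf), n)
  expect_equal(rep1$accuracy, (cf["TP"] + cf["TN"]) / n, ignore_attr = TRUE)
  expect_equal(rep1$recall, cf["TP"] / (cf["TP"] + cf["FN"]),
               ignore_attr = TRUE)
  expect_equal(rep1$specificity, cf["TN"] / (cf["TN"] + cf["FP"]),
               ignore_attr = TRUE)
  expect_identical(rep1$config$positive, "AD")
  expect_identical(svm_loocv(x, y, k = 5, seed = 2)$predictions,
                   rep1$predictions)
})

test_that("label-independent features stay inside the chance band", {
  set.seed(51)
  n <- 40
  y <- factor(rep(c("n", "p"), each = n / 2))
  x <- matrix(rnorm(n * 200), nrow = n)
  rep0 <- svm_loocv(x, y, k = 10, seed = 3)
  band <- 1.96 * sqrt(0.25 / n)
  expect_lt(rep0$accuracy, 0.5 + band + 0.15)
  expect_gte(rep0$accuracy, 0) # and never crashes
})

test_that("a fold losing a class is a design error", {
  y <- factor(c("a", rep("b", 7)))
  x <- matrix(rnorm(8 * 4), nrow = 8)
  expect_error(svm_loocv(x, y, k = 2), "absent")
})

test_that("permutation p-values respect the +1-corrected bounds", {
  set.seed(61)
  n <- 16
  y <- factor(rep(c("HC", "AD"), each = n / 2))
  x <- matrix(rnorm(n * 6), nrow = n)
  x[y == "AD", ] <- x[y == "AD", ] + 8
  pt <- permutation_test(x, y, n_perm = 24, k = 3, seed = 5)
  expect_length(pt$null_accuracies, 24L)
  expect_gte(pt$p_value, 1 / 25)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$observed_accuracy, 1.0)
  expect_lte(pt$p_value, 0.05) # separable signal beats its null
  expect_warning(permutation_test(x, y, n_perm = 5, k = 3, seed = 5),
                 "unstable")
  pt2 <- permutation_test(x, y, n_perm = 24, k = 3, seed = 5)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
})
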