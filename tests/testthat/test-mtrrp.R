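test_that("unit normalization maps range endpoints and is idempotent", {
  expect_equal(normalize_unit(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.3, 1)
  expect_identical(normalize_unit(x), x)
  y <- rnorm(100)
  expect_equal(normalize_unit(normalize_unit(y)), normalize_unit(y))
  expect_error(normalize_unit(c(5, 5, 5)), "constant")
})

test_that("threshold schedule follows eps_min + k*Q*sigma truncated at 1", {
  x <- normalize_unit(rnorm(500))
  sched <- build_schedule(x, eps_min = 0.1, q = 0.3)
  sigma <- attr(sched, "sigma")
  expect_equal(sigma, stats::sd(x))
  k <- seq_along(sched) - 1
  expect_equal(as.numeric(sched), 0.1 + k * 0.3 * sigma)
  expect_true(all(diff(sched) > 0))
  expect_gte(length(sched), 3L)
  expect_lte(max(sched), 1 + 1e-9)
  expect_equal(sched[1], 0.1, ignore_attr = TRUE)
  # a normalized square wave has sd 0.5 (up to the n-1 correction)
  sq <- rep(c(0, 1), 2000)
  s2 <- build_schedule(sq)
  expect_equal(as.numeric(s2), 0.1 + (0:5) * 0.3 * stats::sd(sq))
  expect_error(build_schedule(x, q = 0), "positive")
  expect_error(build_schedule(x, eps_min = 0), "eps_min")
  expect_error(build_schedule(rep(c(0, 1), 100), q = 5), "smaller Q")
  expect_error(build_schedule(rnorm(10) + 5), "normalize")
})

test_that("curves are monotone, bounded and deterministic", {
  for (s in 1:5) {
    x <- generate_reference("white_noise", 1000, seed = s)
    cv <- mtrrp_curve(x, m = 2)
    expect_true(all(diff(cv$rates) >= 0))
    expect_true(all(cv$rates >= 0 & cv$rates <= 1))
    # noise decorrelates fast: recurrences saturate well before eps = 1
    expect_true(any(cv$rates > 0.95 & cv$thresholds < 1))
  }
  x <- generate_fbm(0.6, 3000, seed = 1)
  expect_identical(mtrrp_curve(x), mtrrp_curve(x))
})

test_that("epoched and whole-series curves are close for stationary input", {
  x <- generate_reference("white_noise", 4000, seed = 8)
  c_ep <- mtrrp_curve(x, epoch_length = 1000)
  c_all <- mtrrp_curve(x, epoch_length = Inf)
  expect_equal(c_ep$n_epochs, 4L)
  expect_equal(c_all$n_epochs, 1L)
  expect_equal(c_ep$thresholds, c_all$thresholds)
  expect_lt(max(abs(c_ep$rates - c_all$rates)), 0.05)
})

test_that("an exactly linear curve yields its slope as the gradient", {
  eps <- seq(0.1, 1, by = 0.1)
  cv <- model_curve(eps, alpha = 1, rh = 0) # placeholder container
  cv$rates <- 0.2 + 0.5 * eps
  expect_equal(recurrence_rate_gradient(cv), 0.5)
  expect_equal(recurrence_rate_gradient(cv, fit_strategy = "uniform_max",
                                        uniform_max_eps = 0.45), 0.5)
  cv$rates <- rep(1, length(eps)) # saturated from the first threshold
  expect_error(recurrence_rate_gradient(cv), "fewer than 3")
  expect_error(recurrence_rate_gradient(cv, fit_strategy = "uniform_max"),
               "uniform_max_eps")
})

test_that("Recurrence Hurst inverts the rate model exactly", {
  eps <- seq(0.1, 1, by = 0.06)
  for (alpha in c(0.3, 0.5, 0.8)) {
    for (rh in c(-0.6, -0.1, 0.2, 0.7)) {
      cv <- model_curve(eps, alpha = alpha, rh = rh)
      expect_equal(as.numeric(recurrence_hurst(cv, alpha = alpha)), rh,
                   tolerance = 1e-9)
      expect_equal(as.numeric(recurrence_hurst(cv, aggregate = "mean",
                                               alpha = alpha)), rh,
                   tolerance = 1e-9)
    }
  }
})

test_that("single-point and saturated curves are handled explicitly", {
  cv <- model_curve(0.5, alpha = 0.5, rh = 0) # RR = alpha at one eps < 1
  expect_equal(as.numeric(recurrence_hurst(cv)), 0)
  sat <- model_curve(c(0.2, 0.5, 0.8), alpha = 0.5, rh = 0)
  sat$rates <- rep(1, 3)
  expect_error(recurrence_hurst(sat), "degenerate")
})

test_that("thresholds at eps = 1 are skipped and recorded", {
  eps <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  cv <- model_curve(eps, alpha = 0.5, rh = -0.4)
  rh <- recurrence_hurst(cv)
  expect_equal(as.numeric(rh), -0.4, tolerance = 1e-9)
  expect_equal(attr(rh, "skipped"), 1L)
})

test_that("recurrence complexity is the exact product of its factors", {
  expect_identical(recurrence_complexity(1.5, 0.4), 1.5 * 0.4)
  expect_identical(recurrence_complexity(2.3, 0), 0)
  expect_equal(sign(recurrence_complexity(-1.2, 0.5)), -1)
  expect_error(recurrence_complexity(Inf, 0.5), "finite")
  x <- generate_fbm(0.4, 2000, seed = 9)
  mm <- mtrrp_metrics(x)
  expect_identical(mm$rc, mm$rrg * mm$rh)
})

test_that("the joint model fit recovers planted parameters", {
  eps <- seq(0.1, 0.9, by = 0.05)
  cv <- model_curve(eps, alpha = 0.62, rh = -0.35)
  f <- fit_rr_model(cv)
  expect_equal(f$alpha, 0.62, tolerance = 1e-6)
  expect_equal(f$rh, -0.35, tolerance = 1e-6)
})
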