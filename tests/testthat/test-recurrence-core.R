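test_that("time-delay embedding lays out vectors as expected", {
  ps <- embed_series(1:5, m = 2, tau = 1)
  expect_equal(unclass(ps)[, 1], 1:4, ignore_attr = TRUE)
  expect_equal(unclass(ps)[, 2], 2:5, ignore_attr = TRUE)
  expect_equal(attr(ps, "source_length"), 5L)
  x <- rnorm(20)
  expect_equal(as.numeric(embed_series(x, m = 1, tau = 3)), x)
  ps2 <- embed_series(1:5, m = 3, tau = 2) # exactly one vector fits
  expect_equal(nrow(ps2), 1L)
  expect_equal(as.numeric(ps2), c(1, 3, 5))
  expect_error(embed_series(1:4, m = 3, tau = 2), "too short")
})

test_that("delay selection matches the analytic 1/e crossing for a sine", {
  p <- 64
  x <- generate_reference("harmonic", 4096, params = list(period = p))
  tau <- select_embedding_params(x)$tau
  analytic <- acos(exp(-1)) * p / (2 * pi) # cos(2 pi lag / P) = 1/e
  expect_lte(abs(tau - analytic), 1)
})

test_that("white noise selects delay 1 and a sine embeds in dimension 2", {
  wn <- generate_reference("white_noise", 4096, seed = 3)
  expect_identical(select_embedding_params(wn)$tau, 1L)
  x <- generate_reference("harmonic", 2048, params = list(period = 50))
  cfg <- select_embedding_params(x, fnn_threshold = 0.01)
  expect_identical(cfg$m, 2L)
})

test_that("hand-enumerated recurrence matrix example is reproduced", {
  x <- c(0, 1, 0, 1)
  rm <- recurrence_matrix(x, epsilon = 0.5)
  expect_equal(sum(rm), 8) # 4 diagonal + (1,3),(3,1),(2,4),(4,2)
  expect_equal(rm[1, 3], 1L)
  expect_equal(rm[2, 4], 1L)
  expect_equal(rm[1, 2], 0L)
  expect_equal(recurrence_rate(rm), 0.5)
})

test_that("degenerate thresholds give all-ones and equality-only matrices", {
  ps <- embed_series(rnorm(30), m = 2, tau = 2)
  rm_all <- recurrence_matrix(ps, epsilon = 1e6)
  expect_true(all(rm_all == 1L))
  expect_equal(recurrence_rate(rm_all), 1.0)
  x <- c(1, 2, 1, 3)
  rm0 <- recurrence_matrix(x, epsilon = 0)
  expect_equal(sum(diag(rm0)), 4)
  expect_equal(rm0[1, 3], 1L) # equal values
  expect_equal(sum(rm0), 6)
})

test_that("matrix and rate agree bit-exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(8:40, 1)
    m <- sample(1:3, 1)
    tau <- sample(1:2, 1)
    norm <- sample(c("euclidean", "chebyshev"), 1)
    theiler <- sample(0:2, 1)
    x <- rnorm(n)
    ps <- embed_series(x, m = m, tau = tau)
    eps <- runif(1, 0, 2)
    rm <- recurrence_matrix(ps, eps, norm = norm, theiler = theiler)
    expect_identical(unclass(rm)[, ],
                     oracle_recurrence_matrix(ps, eps, norm, theiler))
    expect_equal(recurrence_rate(rm),
                 oracle_recurrence_rate(ps, eps, norm, theiler))
    expect_equal(recurrence_rates_at(ps, eps, norm = norm,
                                     theiler = theiler),
                 oracle_recurrence_rate(ps, eps, norm, theiler))
  }
})

test_that("recurrence matrices are symmetric with the diagonal rule", {
  set.seed(55)
  ps <- embed_series(rnorm(40), m = 2, tau = 1)
  rm <- recurrence_matrix(ps, 0.4)
  expect_identical(unclass(rm)[, ], t(unclass(rm)[, ]))
  expect_true(all(diag(rm) == 1L))
  rmt <- recurrence_matrix(ps, 0.4, theiler = 2)
  expect_true(all(diag(rmt) == 0L))
  expect_true(all(rmt[abs(row(rmt) - col(rmt)) < 2] == 0L))
})

test_that("norms coincide for one-dimensional embeddings", {
  x <- rnorm(50)
  e1 <- recurrence_matrix(x, 0.3, norm = "euclidean")
  e2 <- recurrence_matrix(x, 0.3, norm = "chebyshev")
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
})

test_that("RR is monotone in the threshold and the ladder backend agrees", {
  set.seed(77)
  ps <- embed_series(rnorm(300), m = 2, tau = 3)
  eps <- c(seq(0.05, 2, by = 0.1), 50) # 50 dwarfs any pairwise distance
  rr_ladder <- recurrence_rates_at(ps, eps)
  expect_true(all(diff(rr_ladder) >= 0))
  expect_equal(rr_ladder[length(eps)], 1.0)
  rr_single <- vapply(eps, function(e) {
    recurrence_rate(recurrence_matrix(ps, e))
  }, numeric(1))
  expect_equal(rr_ladder, rr_single)
})

test_that("large trajectories refuse to materialize but still count", {
  x <- rnorm(6000)
  expect_error(recurrence_matrix(x, 0.5), "not materialized")
  rr <- recurrence_rates_at(embed_series(x, 1, 1), c(0.5, 10))
  expect_true(rr[1] > 0 && rr[2] == 1)
})

test_that("a fully excluding Theiler window is a degenerate input", {
  x <- rnorm(5)
  expect_error(recurrence_rate(recurrence_matrix(x, 1, theiler = 5)),
               "nothing to count")
})
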