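test_that("noiseless inverse-curve data is recovered exactly", {
  x <- 1:10
  fit <- fit_inverse_curve(80 - 20 / x, x)
  expect_equal(fit$a, 80, tolerance = 1e-12)
  expect_equal(fit$b, 20, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$endpoint, 3)   # ceil(20 / 8)

  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 10, 100); b <- runif(1, -30, 60)
    x <- sort(sample(1:30, sample(3:12, 1)))
    fit <- fit_inverse_curve(a - b / x, x)
    expect_equal(fit$a, a, tolerance = 1e-9)
    expect_equal(fit$b, b, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("degenerate series are handled by convention", {
  fit <- fit_inverse_curve(rep(50, 5))
  expect_equal(fit$a, 50)
  expect_equal(fit$b, 0)
  expect_true(is.na(fit$r2))       # R^2 undefined when SS_tot = 0
  expect_equal(fit$endpoint, 1)
  expect_error(fit_inverse_curve(c(1, 2)), "at least 3")
  expect_error(fit_inverse_curve(c(1, 2, 3), c(2, 2, 2)), "distinct")
})

test_that("fits match the grid-refinement least-squares oracle", {
  set.seed(31)
  for (i in 1:15) {
    x <- 1:sample(5:10, 1)
    y <- runif(1, 30, 90) - runif(1, 0, 40) / x + rnorm(length(x), 0, 5)
    fit <- fit_inverse_curve(y, x)
    oracle <- grid_fit_oracle(y, x)
    expect_equal(fit$a, unname(oracle["a"]), tolerance = 1e-6)
    expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-6)
  }
})

test_that("the training endpoint reproduces hand-derived session counts", {
  expect_equal(training_endpoint(79.75, 22.09), 3L)
  expect_equal(training_endpoint(93.587, 22.090), 3L)
  expect_equal(training_endpoint(72.735, 37.968), 6L)
  expect_equal(training_endpoint(77.125, 25.001), 4L)
  expect_equal(training_endpoint(37.21, 15.91, session_offset = 1), 6L)
  expect_equal(training_endpoint(50, 0), 1L)       # plateau met immediately
  expect_equal(training_endpoint(50, -3), 1L)
  expect_equal(training_endpoint(100, 20), 2L)     # exact-integer ratio
  expect_error(training_endpoint(-1, 5), "positive")
})

test_that("the endpoint is monotone in rate and plateau", {
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 5, 100); b <- sort(runif(2, 0, 60))
    expect_true(training_endpoint(a, b[1]) <= training_endpoint(a, b[2]))
    a2 <- sort(runif(2, 5, 100)); b1 <- runif(1, 0, 60)
    expect_true(training_endpoint(a2[2], b1) <= training_endpoint(a2[1], b1))
  }
})

test_that("fitting noisy series recovers the generating parameters", {
  set.seed(97)
  x <- 1:10
  errs <- t(vapply(1:200, function(i) {
    y <- 79.75 - 22.09 / x + rnorm(10, 0, 3)
    fit <- fit_inverse_curve(y, x)
    c(fit$a - 79.75, fit$b - 22.09)
  }, numeric(2)))
  expect_lt(abs(mean(errs[, 1])), 1)       # unbiased plateau
  expect_lt(abs(mean(errs[, 2])), 2)       # unbiased rate
  expect_true(mean(abs(errs[, 1]) <= 5) > 0.95)
  expect_true(mean(abs(errs[, 2]) <= 8) > 0.95)
})

test_that("paired effect sizes match hand computation", {
  res <- effect_size(c(50, 60, 70), c(51, 62, 73))    # diffs 1, 2, 3
  expect_equal(res$es, 2)
  expect_equal(res$magnitude, "large")
  res <- effect_size(c(51, 62, 73), c(50, 60, 70))    # sign symmetry
  expect_equal(res$es, -2)
  expect_equal(res$magnitude, "negative")
  res <- effect_size(c(10, 20, 30), c(15, 25, 35))    # zero-variance diffs
  expect_true(res$undefined)
  expect_true(is.na(res$es))
  expect_error(effect_size(1, 2), "at least 2")
  expect_warning(effect_size(c(1, 2, NA), c(2, 4, 5)), "dropped")
})

test_that("effect size is invariant to a constant score shift", {
  set.seed(41)
  for (i in 1:20) {
    prev <- runif(6, 20, 80); curr <- prev + rnorm(6, 5, 4)
    shift <- runif(1, -50, 50)
    expect_equal(effect_size(prev, curr)$es,
                 effect_size(prev + shift, curr + shift)$es,
                 tolerance = 1e-12)
  }
})

test_that("effect magnitudes use the 0.20 / 0.50 / 0.80 thresholds", {
  expect_equal(classify_effect(c(-0.1, 0, 0.19, 0.2, 0.49, 0.5, 0.8679, 1.942)),
               c("negative", "negligible", "negligible", "small", "small",
                 "medium", "large", "large"))
  expect_error(classify_effect(NA), "finite")
})

test_that("session effect sizes on the worked fixture match hand values", {
  fx <- generate_worked_fixture()
  sc <- score_sessions(fx$session_log, fx$bbt, bounds = fx$bounds)
  es <- session_effect_sizes(sc, "wlif")
  # session 2 diffs: 60 - 35.2 = 24.8 and 70 - 50 = 20
  expect_equal(es$es[es$session == 2], 14 * sqrt(2) / 3)
  expect_equal(es$magnitude[es$session == 2], "large")
  # session 3 diffs are both 10: zero variance, effect undefined
  expect_true(es$undefined[es$session == 3])
})

test_that("fit-table summaries count and average as specified", {
  one <- tibble::tibble(r2 = 1, endpoint = 4L)
  s <- summarize_fits(one)
  expect_equal(s$n_above, 1)
  expect_equal(s$r2_mean, 1)
  expect_equal(s$endpoint_mean_above, 4)
  many <- tibble::tibble(r2 = c(0.1, 0.4, 0.41, 0.9),
                         endpoint = c(1L, 2L, 3L, 5L))
  s <- summarize_fits(many, r2_threshold = 0.4)
  expect_equal(s$n_above, 2)               # strictly greater than 0.4
  expect_equal(s$endpoint_mean_above, 4)
  expect_equal(s$r2_mean, mean(many$r2))
})
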