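test_that("quadrant-change counting matches hand counts", {
  expect_equal(count_quadrant_changes(rep(3L, 22)), 0)
  expect_equal(count_quadrant_changes(c(1, 2, 2, 3)), 2)
  expect_equal(count_quadrant_changes(rep(c(1L, 2L), 11)), 21)
  expect_error(count_quadrant_changes(integer(0)), "empty")
  expect_error(count_quadrant_changes(c(1, 5, 2)), "1..4")
  expect_error(count_quadrant_changes(c(1, NA, 2)), "1..4")
})

test_that("change counts are invariant under quadrant relabelling", {
  set.seed(59)
  for (i in 1:25) {
    seq22 <- sample(1:4, 22, replace = TRUE)
    perm <- sample(1:4)
    expect_equal(count_quadrant_changes(perm[seq22]),
                 count_quadrant_changes(seq22))
  }
})

test_that("session centring removes the column mean and nothing else", {
  expect_equal(unname(normalize_scores(matrix(c(70, 80, 90), ncol = 3))),
               matrix(0, 1, 3))                     # single subject
  out <- normalize_scores(matrix(c(70, 80, 90), ncol = 1))
  expect_equal(as.vector(out), c(-10, 0, 10))
  set.seed(61)
  for (i in 1:20) {
    m <- matrix(runif(24, 0, 100), nrow = 6)
    centred <- normalize_scores(m)
    expect_true(all(abs(colSums(centred)) < 1e-12))
    # between-subject rank order within each session is unchanged
    for (j in seq_len(ncol(m))) {
      expect_equal(order(centred[, j]), order(m[, j]))
    }
  }
})

test_that("grouping by change count averages within groups", {
  rec <- tibble::tibble(q = c(2, 2), wlif_norm = c(5, -5))
  expect_equal(group_by_q(rec)$mean, 0)
  rec <- tibble::tibble(q = c(1, 1, 3), wlif_norm = c(4, 6, -2))
  g <- group_by_q(rec)
  expect_equal(g$q, c(1, 3))
  expect_equal(g$mean, c(5, -2))
  expect_equal(g$n, c(2L, 1L))
  rec <- tibble::tibble(q = 1:4, wlif_norm = c(3, 1, 4, 1))
  expect_equal(group_by_q(rec)$mean, c(3, 1, 4, 1))  # singleton groups
})

test_that("count-weighted group means conserve the grand mean", {
  set.seed(67)
  for (i in 1:20) {
    rec <- tibble::tibble(q = sample(0:8, 40, replace = TRUE),
                          wlif_norm = rnorm(40, 0, 10))
    g <- group_by_q(rec)
    expect_equal(sum(g$mean * g$n) / sum(g$n), mean(rec$wlif_norm),
                 tolerance = 1e-12)
  }
})

test_that("the grouped regression matches the normal-equations oracle", {
  g <- tibble::tibble(q = 0:5, mean = 2 * (0:5) + 1, n = 1L)
  res <- regress_q_vs_score(g)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$r2, 1)

  flat <- tibble::tibble(q = 0:3, mean = rep(2.5, 4), n = 1L)
  res <- regress_q_vs_score(flat)
  expect_equal(res$slope, 0)
  expect_true(is.na(res$r))

  set.seed(71)
  for (i in 1:20) {
    g <- tibble::tibble(q = sample(0:15, 6), mean = rnorm(6, 0, 5), n = 1L)
    res <- regress_q_vs_score(g)
    oracle <- ols_oracle(g$q, g$mean)
    expect_equal(res$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(res$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-10)
    expect_equal(res$r, stats::cor(g$q, g$mean), tolerance = 1e-10)
    expect_equal(res$r2, res$r^2, tolerance = 1e-10)
  }
  expect_error(regress_q_vs_score(tibble::tibble(q = 1, mean = 1, n = 1L)),
               "at least 2")
})

test_that("end-to-end analysis links counts to centred scores", {
  cfg <- cohort_config(n_subjects = 4, n_sessions = 5, seed = 303)
  co <- generate_cohort(cfg)
  sc <- score_sessions(co$session_log)
  prep <- preposition_analysis(co$session_log, sc)
  expect_equal(nrow(prep$records), 20)               # 4 subjects x 5 sessions
  expect_true(all(prep$records$q >= 0 & prep$records$q <= 21))
  # centred scores sum to zero within each session
  sums <- tapply(prep$records$wlif_norm, prep$records$session, sum)
  expect_true(all(abs(sums) < 1e-9))
  expect_equal(sum(prep$grouped$n), 20)
  expect_true(is.finite(prep$regression$slope))
})

test_that("independent prepositioning yields a slope centred on zero", {
  # performance and quadrant switching are generated independently, so the
  # regression slope should scatter around zero across cohorts
  set.seed(83)
  slopes <- vapply(1:40, function(i) {
    co <- generate_cohort(cohort_config(n_subjects = 6, n_sessions = 6,
                                        seed = 9000 + i))
    sc <- score_sessions(co$session_log)
    preposition_analysis(co$session_log, sc)$regression$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 4 * se + 0.05)
})
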