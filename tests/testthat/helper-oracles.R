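# Brute-force grid-refinement least-squares oracle for the inverse-curve
# model: repeatedly evaluates the SSE surface on an (a, b) grid and zooms on
# the minimum. Each round re-centres the residuals at the current best point
# and searches offsets (da, db), so the surface is evaluated without
# large-term cancellation. Independent of the lm-based fitting path.
grid_fit_oracle <- function(y, x, rounds = 45, grid_n = 41) {
  n <- length(y)
  sx <- sum(1 / x); sxx <- sum(1 / x^2)
  best <- c(mean(y), 0)
  half_a <- diff(range(y)) + 60
  half_b <- 120
  for (r in seq_len(rounds)) {
    r0 <- y - best[1] + best[2] / x
    s0 <- sum(r0); s1 <- sum(r0 / x)
    das <- seq(-half_a, half_a, length.out = grid_n)
    dbs <- seq(-half_b, half_b, length.out = grid_n)
    # SSE(best + d) minus the constant term, exact quadratic in (da, db)
    surf <- outer(das, dbs, function(da, db) {
      da^2 * n + db^2 * sxx - 2 * da * s0 + 2 * db * s1 - 2 * da * db * sx
    })
    idx <- arrayInd(which.min(surf), dim(surf))
    best <- best + c(das[idx[1]], dbs[idx[2]])
    # halve the window when the minimum is interior; otherwise keep the
    # width and crawl along the correlated SSE valley
    if (all(idx > 2) && all(idx < grid_n - 1)) {
      half_a <- half_a / 2
      half_b <- half_b / 2
    }
  }
  c(a = best[1], b = best[2])
}

# Closed-form simple-regression slope/intercept from the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# A complete one-subject session log at the given times (one per task).
make_session_log <- function(times, subject = "S01", session = 1,
                             bounds = default_bounds(), dnf = NULL) {
  if (is.null(dnf)) dnf <- as.integer(is.na(times))
  tibble::tibble(subject_id = subject, session = session,
                 task_id = bounds$task_id, time_s = times, dnf = dnf,
                 quadrant = 1L)
}
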