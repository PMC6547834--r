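#' Fit the inverse learning-curve model to a score series
#'
#' Fits `Y = a - b/X`, the standard inverse learning-curve model, where `a`
#' is the learning plateau (asymptotic performance) and `b` the learning
#' rate (magnitude of initial gains). The model is linear in the basis
#' `{1, 1/X}`, so the least-squares solution is computed exactly with
#' ordinary linear regression rather than iterative optimisation; the result
#' is deterministic and identical to a nonlinear fit of the same model.
#'
#' `X` is the administration index. For measures not administered in every
#' session (the BBT starts in session 2), `session_offset` maps index to
#' session number: `session = X + session_offset`.
#'
#' @param y Numeric outcome scores.
#' @param x Administration indexes (default `1..length(y)`); strictly
#'   positive, at least two distinct values.
#' @param session_offset Integer offset from administration index to session
#'   number (0 for the mSHAP indexes, 1 for the BBT).
#' @param endpoint_fraction Plateau fraction defining the training endpoint
#'   (default 0.9).
#' @return An object of class `learning_curve_fit`: a list with elements
#'   `a`, `b`, `r2` (`NA` for a constant series, where R-squared is
#'   undefined), `endpoint` (session number), `session_offset`, `n`.
#' @export
#' @examples
#' x <- 1:10
#' fit_inverse_curve(80 - 20 / x, x)  # recovers a = 80, b = 20, r2 = 1
fit_inverse_curve <- function(y, x = seq_along(y), session_offset = 0L,
                              endpoint_fraction = 0.9) {
  ok <- complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 points to fit", call. = FALSE)
  if (length(unique(x)) < 2) stop("need at least 2 distinct x", call. = FALSE)
  if (any(x <= 0)) stop("administration index must be positive",
                        call. = FALSE)

  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    a <- y[1]; b <- 0; r2 <- NA_real_
  } else {
    cf <- coef(lm(y ~ I(1 / x)))
    a <- unname(cf[1]); b <- -unname(cf[2])
    ss_res <- sum((y - (a - b / x))^2)
    r2 <- 1 - ss_res / ss_tot
  }
  endpoint <- if (a > 0) {
    training_endpoint(a, b, session_offset, endpoint_fraction)
  } else {
    NA_integer_
  }
  structure(
    list(a = a, b = b, r2 = r2, endpoint = endpoint,
         session_offset = as.integer(session_offset), n = length(y)),
    class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat("Inverse learning-curve fit (Y = a - b/X)\n")
  cat(sprintf("  plateau a = %.3f, rate b = %.3f, R^2 = %s (n = %d)\n",
              x$a, x$b,
              if (is.na(x$r2)) "undefined" else sprintf("%.3f", x$r2), x$n))
  cat(sprintf("  training endpoint (90%% of plateau): session %s\n",
              ifelse(is.na(x$endpoint), "undefined", x$endpoint)))
  invisible(x)
}

#' Training endpoint from learning-curve parameters
#'
#' The training endpoint is the first session whose fitted score reaches a
#' stated fraction (by default 90%) of the learning plateau: the smallest
#' integer `X >= 1` with `a - b/X >= fraction * a`, i.e.
#' `ceiling(b / ((1 - fraction) * a))`, shifted by `session_offset` to the
#' session scale. A non-positive learning rate means the plateau is met at
#' the first administration.
#'
#' @param a Learning plateau(s), `> 0`.
#' @param b Learning rate(s).
#' @param session_offset Integer offset from administration index to session
#'   number.
#' @param fraction Plateau fraction in (0, 1); default 0.9.
#' @return Integer session number(s). Vectorised over `a` and `b`.
#' @export
#' @examples
#' training_endpoint(79.75, 22.09)                      # 3 sessions
#' training_endpoint(37.21, 15.91, session_offset = 1)  # 6 sessions
training_endpoint <- function(a, b, session_offset = 0L, fraction = 0.9) {
  if (any(a <= 0)) stop("plateau must be positive", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)",
                                           call. = FALSE)
  ratio <- b / ((1 - fraction) * a)
  # tolerate floating error when the ratio lands exactly on an integer
  k <- pmax(1, ceiling(ratio - 1e-9))
  as.integer(k + session_offset)
}

#' Fit learning curves for every scoring category
#'
#' Builds the per-category fit table: the weighted summary index (`wlif`),
#' the BBT mean (administration index 1..K maps to sessions 2..K+1), the six
#' pattern indexes, and each task score. By default each category's series
#' is the cross-subject session mean; `pooled = TRUE` instead fits all
#' individual subject-session points jointly.
#'
#' @param session_scores Output of [score_sessions()].
#' @param task_scores Optional output of [score_tasks()]; when supplied,
#'   per-task fits (`ts_*` categories) are included.
#' @param pooled Fit pooled individual points instead of session means.
#' @param endpoint_fraction Plateau fraction for the endpoint (default 0.9).
#' @return A tibble with columns `category`, `measure`, `plateau`, `rate`,
#'   `r2`, `endpoint`, `session_offset`, `n_points`.
#' @export
fit_score_table <- function(session_scores, task_scores = NULL,
                            pooled = FALSE, endpoint_fraction = 0.9) {
  series <- list()
  add <- function(category, measure, y, x, offset) {
    series[[category]] <<- list(category = category, measure = measure,
                                y = y, x = x, offset = offset)
  }
  collapse <- function(y, x) {
    if (pooled) list(y = y, x = x)
    else {
      m <- tapply(y, x, mean, na.rm = TRUE)
      list(y = as.vector(m), x = as.numeric(names(m)))
    }
  }

  s <- collapse(session_scores$wlif, session_scores$session)
  add("wlif", "wlif", s$y, s$x, 0L)

  if ("bbt_mean" %in% names(session_scores)) {
    keep <- !is.na(session_scores$bbt_mean)
    if (any(keep)) {
      s <- collapse(session_scores$bbt_mean[keep],
                    session_scores$session[keep] - 1L)
      add("bbt", "bbt", s$y, s$x, 1L)
    }
  }

  for (pp in pattern_levels) {
    col <- paste0("lif_", pp)
    s <- collapse(session_scores[[col]], session_scores$session)
    add(paste0("lif_", pp), "lif", s$y, s$x, 0L)
  }

  if (!is.null(task_scores)) {
    for (task in unique(task_scores$task_id)) {
      sel <- task_scores$task_id == task
      s <- collapse(task_scores$ts[sel], task_scores$session[sel])
      add(paste0("ts_", task), "ts", s$y, s$x, 0L)
    }
  }

  rows <- lapply(series, function(sr) {
    fit <- fit_inverse_curve(sr$y, sr$x, session_offset = sr$offset,
                             endpoint_fraction = endpoint_fraction)
    tibble::tibble(category = sr$category, measure = sr$measure,
                   plateau = fit$a, rate = fit$b, r2 = fit$r2,
                   endpoint = fit$endpoint,
                   session_offset = fit$session_offset, n_points = fit$n)
  })
  dplyr::bind_rows(rows)
}

#' Summarise a table of learning-curve fits
#'
#' Reports, for a set of per-category fits, the mean and SD of R-squared
#' over all fits, how many exceed a goodness-of-fit threshold, and the mean
#' and SD of the training endpoint among those exceeding it.
#'
#' @param fits A fit table with columns `r2` and `endpoint` (e.g. from
#'   [fit_score_table()] or [reference_fits()]).
#' @param r2_threshold Goodness-of-fit threshold (default 0.4, the
#'   conventional cut for a moderate-to-strong fit).
#' @return A one-row tibble: `n`, `r2_mean`, `r2_sd`, `n_above`,
#'   `endpoint_mean_above`, `endpoint_sd_above`.
#' @export
#' @examples
#' fits <- dplyr::filter(reference_fits(), measure == "ts")
#' summarize_fits(fits)
summarize_fits <- function(fits, r2_threshold = 0.4) {
  stopifnot(nrow(fits) > 0)
  above <- !is.na(fits$r2) & fits$r2 > r2_threshold
  tibble::tibble(
    n = nrow(fits),
    r2_mean = mean(fits$r2, na.rm = TRUE),
    r2_sd = sd(fits$r2, na.rm = TRUE),
    n_above = sum(above),
    endpoint_mean_above = if (any(above)) mean(fits$endpoint[above])
                          else NA_real_,
    endpoint_sd_above = if (sum(above) > 1) sd(fits$endpoint[above])
                        else NA_real_)
}
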