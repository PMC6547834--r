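#' Count terminal-device orientation changes in an assessment
#'
#' The terminal device's orientation is recorded per task as one of four
#' 90-degree quadrants. The quadrant-change count — the number of adjacent
#' task pairs with differing quadrants — is the proxy for how much the user
#' exploited prepositioning during the assessment.
#'
#' @param quadrants Integer vector of quadrant codes in `1..4`, one per task
#'   in administration order.
#' @return Integer change count in `0..(length(quadrants) - 1)`.
#' @export
#' @examples
#' count_quadrant_changes(c(1, 2, 2, 3))  # 2
count_quadrant_changes <- function(quadrants) {
  if (length(quadrants) == 0) stop("empty quadrant sequence", call. = FALSE)
  if (anyNA(quadrants) || !all(quadrants %in% 1:4)) {
    stop("quadrant codes must be integers in 1..4", call. = FALSE)
  }
  sum(diff(as.integer(quadrants)) != 0)
}

#' Centre scores on their session mean
#'
#' Removes the session effect from a subjects-by-sessions score matrix by
#' subtracting each session's (column) mean, so that each column of the
#' result sums to zero and subjects are compared to the cohort at the same
#' stage of training.
#'
#' @param score_matrix Numeric matrix, subjects in rows, sessions in
#'   columns.
#' @return A matrix of session-centred scores.
#' @export
normalize_scores <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  if (any(colSums(!is.na(score_matrix)) == 0)) {
    stop("a session has no scores to centre on", call. = FALSE)
  }
  sweep(score_matrix, 2, colMeans(score_matrix, na.rm = TRUE))
}

#' Group session-centred scores by quadrant-change count
#'
#' Pools every (subject, session) observation with the same quadrant-change
#' count and averages the centred scores within each count.
#'
#' @param records Tibble with columns `q` (quadrant-change count) and
#'   `wlif_norm` (session-centred score).
#' @return A tibble with one row per distinct `q`: `q`, `mean`, `se`
#'   (standard error; `NA` for singleton groups), `n`.
#' @export
group_by_q <- function(records) {
  if (nrow(records) == 0) stop("no prepositioning records", call. = FALSE)
  records |>
    dplyr::group_by(q = .data$q) |>
    dplyr::summarise(mean = mean(.data$wlif_norm),
                     se = sd(.data$wlif_norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$q)
}

#' Regress grouped centred scores on quadrant-change count
#'
#' Ordinary least-squares line through the (q, group mean) points, testing
#' whether more prepositioning is associated with above-average performance.
#' The regression is unweighted by default (each group mean counts once);
#' `weighted = TRUE` weights groups by their observation counts. The Pearson
#' correlation is reported alongside slope and R-squared because the three
#' answer different questions about the association.
#'
#' @param grouped Output of [group_by_q()] (columns `q`, `mean`, and `n` if
#'   weighting).
#' @param weighted Weight group means by group size.
#' @return A list with `slope`, `intercept`, `r` (`NA` when the group means
#'   have zero variance), `r2`, `n_groups`.
#' @export
regress_q_vs_score <- function(grouped, weighted = FALSE) {
  if (length(unique(grouped$q)) < 2) {
    stop("need at least 2 distinct quadrant-change groups", call. = FALSE)
  }
  w <- if (weighted) grouped$n else rep(1, nrow(grouped))
  fit <- lm(mean ~ q, data = grouped, weights = w)
  slope <- unname(coef(fit)[2])
  if (sd(grouped$mean) == 0) {
    r <- NA_real_; r2 <- 0; slope <- 0
  } else {
    ss_res <- sum(w * stats::residuals(fit)^2)
    ss_tot <- sum(w * (grouped$mean - stats::weighted.mean(grouped$mean,
                                                           w))^2)
    r2 <- 1 - ss_res / ss_tot
    r <- if (weighted) sign(slope) * sqrt(max(r2, 0))
         else stats::cor(grouped$q, grouped$mean)
  }
  list(slope = slope, intercept = unname(coef(fit)[1]), r = r, r2 = r2,
       n_groups = length(unique(grouped$q)))
}

#' End-to-end prepositioning analysis
#'
#' From a session log with per-task quadrant records and the matching
#' session scores: counts quadrant changes per subject-session, centres the
#' summary scores on their session means, groups the centred scores by
#' change count, and fits the unweighted regression of group mean on count.
#'
#' @param session_log Long-format session log including a `quadrant` column.
#' @param session_scores Output of [score_sessions()] for the same cohort.
#' @param weighted Passed to [regress_q_vs_score()].
#' @return A list with `records` (per subject-session `q` and `wlif_norm`),
#'   `grouped` (per-`q` means), and `regression`.
#' @export
preposition_analysis <- function(session_log, session_scores,
                                 weighted = FALSE) {
  q_tbl <- session_log |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(q = count_quadrant_changes(.data$quadrant),
                     .groups = "drop")

  wide <- session_scores |>
    dplyr::select("subject_id", "session", "wlif") |>
    tidyr::pivot_wider(names_from = "session", values_from = "wlif")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$subject_id
  centred <- normalize_scores(mat)

  norm_tbl <- tibble::as_tibble(centred, rownames = "subject_id") |>
    tidyr::pivot_longer(-"subject_id", names_to = "session",
                        values_to = "wlif_norm") |>
    dplyr::mutate(session = as.integer(.data$session))
  if (is.numeric(session_scores$subject_id)) {
    norm_tbl$subject_id <- as.numeric(norm_tbl$subject_id)
  }

  records <- dplyr::inner_join(q_tbl, norm_tbl,
                               by = c("subject_id", "session"))
  grouped <- group_by_q(records)
  list(records = records, grouped = grouped,
       regression = regress_q_vs_score(grouped, weighted = weighted))
}
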