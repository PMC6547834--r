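#' Scale a task completion time to a 0-100 task score
#'
#' Linearly rescales a completion time between the task's normative boundary
#' `n` (average normative time, scoring 100) and `m` (eight times normative,
#' scoring 0): `ts = 100 * (m - t) / (m - n)`. Times faster than `n` clamp to
#' 100 and times slower than `m` clamp to 0, keeping scores on the stated
#' 0-100 scale. Unsuccessful attempts (DNF) score 0 regardless of time.
#'
#' @param time Completion time in seconds (vectorised). May be `NA` for DNF
#'   attempts.
#' @param n_lower Lower boundary in seconds (normal function), `> 0`.
#' @param m_upper Upper boundary in seconds (minimal function), `> n_lower`.
#' @param dnf Logical; did-not-finish flag. Defaults to `is.na(time)`.
#' @return Numeric vector of task scores in `[0, 100]`.
#' @export
#' @examples
#' scale_task_score(22.5, n_lower = 5, m_upper = 40)  # 50
#' scale_task_score(NA, 5, 40)                        # DNF -> 0
scale_task_score <- function(time, n_lower, m_upper, dnf = is.na(time)) {
  if (any(n_lower <= 0) || any(m_upper <= n_lower)) {
    stop("bounds must satisfy 0 < n_lower < m_upper", call. = FALSE)
  }
  if (any(!dnf & is.na(time))) {
    stop("time is missing for an attempt not flagged DNF", call. = FALSE)
  }
  if (any(time < 0, na.rm = TRUE)) {
    stop("negative task time", call. = FALSE)
  }
  ts <- 100 * (m_upper - time) / (m_upper - n_lower)
  ts <- pmin(pmax(ts, 0), 100)
  ts[dnf] <- 0
  ts
}

#' Linear index of functionality for one prehensile pattern
#'
#' The LIF for a pattern is the arithmetic mean of the task scores of the
#' tasks mapped to that pattern.
#'
#' @param task_scores Tibble/data frame with columns `task_id`, `ts`.
#' @param pattern One of the six prehensile-pattern labels.
#' @param task_patterns Task-to-pattern mapping (see
#'   [default_task_patterns()]).
#' @return The pattern score in `[0, 100]`.
#' @export
compute_lif <- function(task_scores, pattern,
                        task_patterns = default_task_patterns()) {
  stopifnot(pattern %in% pattern_levels)
  members <- task_patterns$task_id[task_patterns$pattern == pattern]
  sel <- task_scores$task_id %in% members
  if (!any(sel)) {
    stop("no scored tasks mapped to pattern '", pattern, "'", call. = FALSE)
  }
  mean(task_scores$ts[sel])
}

#' Weighted linear index of functionality
#'
#' Combines the six pattern indexes into a single summary score, weighting
#' each pattern by its number of member tasks and dividing by the total
#' membership count (3, 3, 6, 5, 5, 3 over 25 with the default mapping).
#' Six equal pattern scores therefore yield exactly that common value.
#'
#' @param lifs Named numeric vector of the six pattern scores (names are the
#'   pattern labels).
#' @param weights Named integer weights per pattern (see
#'   [pattern_weights()]).
#' @return The weighted summary score in `[0, 100]`.
#' @export
#' @examples
#' lifs <- c(spherical = 100, tripod = 100, power = 0, lateral = 0,
#'           tip = 0, extension = 100)
#' compute_wlif(lifs)  # (300 + 300 + 300) / 25 = 36
compute_wlif <- function(lifs, weights = pattern_weights()) {
  missing <- setdiff(names(weights), names(lifs))
  if (length(missing)) {
    stop("missing pattern score(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(weights * lifs[names(weights)]) / sum(weights)
}

#' Mean Box and Blocks Test score for a session
#'
#' The session score is the mean number of blocks transported per minute
#' across the (normally three) trials. A session with fewer recorded trials
#' is averaged over what is available rather than dropped.
#'
#' @param trials Nonnegative integer block counts, one per trial.
#' @return Mean blocks per minute.
#' @export
#' @examples
#' score_bbt(c(28, 31, 34))  # 31
score_bbt <- function(trials) {
  if (length(trials) == 0) stop("no BBT trials recorded", call. = FALSE)
  if (any(is.na(trials)) || any(trials < 0)) {
    stop("BBT trial counts must be nonnegative", call. = FALSE)
  }
  mean(trials)
}

#' Score every task attempt in a session log
#'
#' Adds a `ts` column of 0-100 task scores to a long-format session log.
#'
#' @param session_log Tibble with columns `subject_id`, `session`, `task_id`,
#'   `time_s` (`NA` for DNF), `dnf` (logical or 0/1). A `quadrant` column, if
#'   present, is carried through.
#' @param bounds Normative-bounds table (see [default_bounds()]).
#' @return The input with an added `ts` column.
#' @export
score_tasks <- function(session_log, bounds = default_bounds()) {
  validate_bounds(bounds)
  idx <- match(session_log$task_id, bounds$task_id)
  if (anyNA(idx)) {
    stop("task_id without normative bounds: ",
         paste(unique(session_log$task_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(session_log,
                ts = scale_task_score(.data$time_s,
                                      bounds$n_lower_s[idx],
                                      bounds$m_upper_s[idx],
                                      dnf = as.logical(.data$dnf)))
}

#' Per-session functional scores for a cohort
#'
#' Scores a long-format session log into one row per subject-session:
#' the six pattern indexes (`lif_*` columns), the weighted summary index
#' `wlif`, the number of DNF attempts, and — when a BBT log is supplied —
#' the mean blocks per minute `bbt_mean` (`NA` for sessions without BBT
#' trials, e.g. the first training session).
#'
#' @inheritParams score_tasks
#' @param bbt Optional tibble with columns `subject_id`, `session`, `trial`,
#'   `blocks`.
#' @param task_patterns Task-to-pattern mapping (see
#'   [default_task_patterns()]).
#' @return A tibble with one row per subject-session.
#' @export
score_sessions <- function(session_log, bbt = NULL,
                           bounds = default_bounds(),
                           task_patterns = default_task_patterns()) {
  validate_task_patterns(task_patterns)
  scored <- score_tasks(session_log, bounds)
  weights <- pattern_weights(task_patterns)

  lifs <- scored |>
    dplyr::inner_join(task_patterns, by = "task_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$subject_id, .data$session, .data$pattern) |>
    dplyr::summarise(lif = mean(.data$ts), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "lif",
                       names_prefix = "lif_")

  lif_cols <- paste0("lif_", pattern_levels)
  missing <- setdiff(lif_cols, names(lifs))
  if (length(missing)) {
    stop("session log covers no task for pattern(s): ",
         paste(sub("^lif_", "", missing), collapse = ", "), call. = FALSE)
  }

  lif_mat <- as.matrix(lifs[lif_cols])
  lifs$wlif <- as.vector(lif_mat %*% weights[pattern_levels]) / sum(weights)

  dnf_tbl <- scored |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(n_dnf = sum(as.logical(.data$dnf)), .groups = "drop")
  out <- dplyr::left_join(lifs, dnf_tbl, by = c("subject_id", "session"))

  if (!is.null(bbt)) {
    bbt_tbl <- bbt |>
      dplyr::group_by(.data$subject_id, .data$session) |>
      dplyr::summarise(bbt_mean = score_bbt(.data$blocks), .groups = "drop")
    out <- dplyr::left_join(out, bbt_tbl, by = c("subject_id", "session"))
  }
  dplyr::arrange(out, .data$subject_id, .data$session)
}
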