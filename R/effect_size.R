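#' Paired-session effect size
#'
#' Quantifies the impact of one additional training session as the mean of
#' the paired per-subject score differences divided by the standard
#' deviation of those differences (sample SD, n-1 denominator by default).
#' A zero-variance set of differences leaves the effect size undefined
#' (`NA` with `undefined = TRUE`) rather than infinite.
#'
#' @param scores_prev,scores_curr Numeric score vectors paired by subject
#'   (same order); at least 2 pairs. Pairs with a missing value are dropped
#'   with a warning.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population
#'   SD) for the denominator of the standardiser.
#' @return A list with `es`, `magnitude` (see [classify_effect()]),
#'   `mean_diff`, `sd_diff`, `n_pairs`, `undefined`.
#' @export
#' @examples
#' effect_size(c(50, 60, 70), c(51, 62, 73))  # diffs 1,2,3 -> es = 2, large
effect_size <- function(scores_prev, scores_curr,
                        sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(length(scores_prev) == length(scores_curr))
  ok <- complete.cases(scores_prev, scores_curr)
  if (!all(ok)) {
    warning(sum(!ok), " unpaired subject(s) dropped from effect size")
  }
  d <- scores_curr[ok] - scores_prev[ok]
  if (length(d) < 2) stop("need at least 2 paired scores", call. = FALSE)
  s <- sd(d)
  if (sd_denominator == "n") s <- s * sqrt((length(d) - 1) / length(d))
  if (s == 0) {
    return(list(es = NA_real_, magnitude = NA_character_,
                mean_diff = mean(d), sd_diff = 0, n_pairs = length(d),
                undefined = TRUE))
  }
  es <- mean(d) / s
  list(es = es, magnitude = classify_effect(es), mean_diff = mean(d),
       sd_diff = s, n_pairs = length(d), undefined = FALSE)
}

#' Classify an effect size magnitude
#'
#' Conventional thresholds: 0.20, 0.50 and 0.80 mark the onset of small,
#' medium and large effects. A negative value indicates a performance
#' decrease; values in `[0, 0.20)` are negligible. Boundaries are inclusive
#' upward (0.20 is small, 0.80 is large).
#'
#' @param es Finite effect size(s).
#' @return Character vector: `"negative"`, `"negligible"`, `"small"`,
#'   `"medium"` or `"large"`.
#' @export
#' @examples
#' classify_effect(c(-0.1, 0.1, 0.2, 0.6, 0.8679))
classify_effect <- function(es) {
  stopifnot(all(is.finite(es)))
  cut(es, breaks = c(-Inf, 0, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negative", "negligible", "small", "medium", "large")) |>
    as.character()
}

#' Session-by-session effect sizes for a cohort
#'
#' Computes the paired effect size of each session relative to the previous
#' administration of the same measure, starting with the second
#' administration.
#'
#' @param session_scores Output of [score_sessions()].
#' @param measure Column of `session_scores` to analyse (`"wlif"`,
#'   `"bbt_mean"`, or any `lif_*` column).
#' @inheritParams effect_size
#' @return A tibble with one row per session after the first administration:
#'   `session`, `es`, `magnitude`, `n_pairs`, `undefined`.
#' @export
session_effect_sizes <- function(session_scores, measure = "wlif",
                                 sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(measure %in% names(session_scores))
  wide <- session_scores |>
    dplyr::select("subject_id", "session", dplyr::all_of(measure)) |>
    dplyr::filter(!is.na(.data[[measure]])) |>
    tidyr::pivot_wider(names_from = "session",
                       values_from = dplyr::all_of(measure))
  sessions <- sort(as.integer(setdiff(names(wide), "subject_id")))
  rows <- lapply(seq_along(sessions)[-1], function(k) {
    res <- effect_size(wide[[as.character(sessions[k - 1])]],
                       wide[[as.character(sessions[k])]],
                       sd_denominator = sd_denominator)
    tibble::tibble(session = sessions[k], es = res$es,
                   magnitude = res$magnitude, n_pairs = res$n_pairs,
                   undefined = res$undefined)
  })
  dplyr::bind_rows(rows)
}
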