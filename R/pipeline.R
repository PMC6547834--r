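#' Run the full training-assessment pipeline
#'
#' From a session log (and optionally a BBT log) to the complete analysis:
#' per-session functional scores, the per-category learning-curve fit table
#' with training endpoints, session-by-session effect sizes for the summary
#' index and the BBT, and the prepositioning analysis. Deterministic given
#' its inputs.
#'
#' @param session_log Session-log tibble or CSV path.
#' @param bbt Optional BBT tibble or CSV path.
#' @param bounds Normative-bounds tibble or CSV path.
#' @param task_patterns Task-to-pattern mapping tibble.
#' @param r2_threshold Goodness-of-fit threshold for the fit summary.
#' @param endpoint_fraction Plateau fraction defining the endpoint.
#' @param sd_denominator Effect-size standardiser denominator
#'   (see [effect_size()]).
#' @param weighted_regression Weight the prepositioning regression by group
#'   size.
#' @param pooled Fit learning curves to pooled individual points rather
#'   than session means.
#' @return A `bypasstrain_report` list: `session_scores`, `task_scores`,
#'   `fits`, `fit_summary` (per measure), `effect_sizes` (per measure),
#'   `preposition`, and `summary` (headline numbers).
#' @export
run_pipeline <- function(session_log, bbt = NULL,
                         bounds = default_bounds(),
                         task_patterns = default_task_patterns(),
                         r2_threshold = 0.4, endpoint_fraction = 0.9,
                         sd_denominator = "n-1",
                         weighted_regression = FALSE, pooled = FALSE) {
  if (is.character(session_log)) session_log <- read_session_log(session_log)
  if (is.character(bbt)) bbt <- read_bbt_log(bbt)
  if (is.character(bounds)) bounds <- read_bounds(bounds)

  val <- validate_inputs(session_log, bbt, bounds)
  if (!val$pass) {
    stop("input validation failed with ", nrow(val$findings),
         " finding(s); run validate_inputs() for details", call. = FALSE)
  }

  task_scores <- score_tasks(session_log, bounds)
  session_scores <- score_sessions(session_log, bbt, bounds, task_patterns)
  fits <- fit_score_table(session_scores, task_scores, pooled = pooled,
                          endpoint_fraction = endpoint_fraction)

  fit_summary <- fits |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(~ summarize_fits(.x, r2_threshold)) |>
    dplyr::ungroup()

  effects <- list(
    wlif = session_effect_sizes(session_scores, "wlif",
                                sd_denominator = sd_denominator))
  if ("bbt_mean" %in% names(session_scores)) {
    effects$bbt <- session_effect_sizes(session_scores, "bbt_mean",
                                        sd_denominator = sd_denominator)
  }

  prep <- preposition_analysis(session_log, session_scores,
                               weighted = weighted_regression)

  pick <- function(cat, col) {
    v <- fits[[col]][fits$category == cat]
    if (length(v)) v else NA_real_
  }
  summary <- list(
    n_subjects = dplyr::n_distinct(session_scores$subject_id),
    n_sessions = dplyr::n_distinct(session_scores$session),
    wlif_plateau = pick("wlif", "plateau"),
    wlif_rate = pick("wlif", "rate"),
    wlif_r2 = pick("wlif", "r2"),
    wlif_endpoint = pick("wlif", "endpoint"),
    bbt_plateau = pick("bbt", "plateau"),
    bbt_rate = pick("bbt", "rate"),
    bbt_r2 = pick("bbt", "r2"),
    bbt_endpoint = pick("bbt", "endpoint"),
    preposition_slope = prep$regression$slope,
    preposition_r = prep$regression$r,
    preposition_r2 = prep$regression$r2)

  structure(list(session_scores = session_scores,
                 task_scores = task_scores, fits = fits,
                 fit_summary = fit_summary, effect_sizes = effects,
                 preposition = prep, summary = summary),
            class = "bypasstrain_report")
}

#' @export
print.bypasstrain_report <- function(x, ...) {
  s <- x$summary
  cat("Training-assessment report:",
      s$n_subjects, "subjects x", s$n_sessions, "sessions\n")
  cat(sprintf(
    "  wLIF: plateau %.2f, rate %.2f, R^2 %.2f, endpoint session %d\n",
    s$wlif_plateau, s$wlif_rate, s$wlif_r2, s$wlif_endpoint))
  if (!is.na(s$bbt_plateau)) {
    cat(sprintf(
      "  BBT : plateau %.2f, rate %.2f, R^2 %.2f, endpoint session %d\n",
      s$bbt_plateau, s$bbt_rate, s$bbt_r2, s$bbt_endpoint))
  }
  cat(sprintf("  prepositioning: slope %.3f, r %.3f, R^2 %.3f\n",
              s$preposition_slope, s$preposition_r, s$preposition_r2))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the report's tables as CSV (session scores, fit table, effect
#' sizes, prepositioning grouped means) and the headline numbers plus the
#' regression summary as machine-readable JSON.
#'
#' @param report A `bypasstrain_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bypasstrain_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(session_scores = file.path(dir, "session_scores.csv"),
             fits = file.path(dir, "fits.csv"),
             effect_sizes = file.path(dir, "effect_sizes.csv"),
             preposition_groups = file.path(dir, "preposition_groups.csv"),
             summary = file.path(dir, "summary.json"))
  readr::write_csv(report$session_scores, paths["session_scores"])
  readr::write_csv(report$fits, paths["fits"])
  effects <- dplyr::bind_rows(report$effect_sizes, .id = "measure")
  readr::write_csv(effects, paths["effect_sizes"])
  readr::write_csv(report$preposition$grouped, paths["preposition_groups"])
  jsonlite::write_json(c(report$summary,
                         list(preposition = report$preposition$regression)),
                       paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
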