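#' Read a session log CSV
#'
#' Long-format log of mSHAP task attempts: one row per subject, session and
#' task, with columns `subject_id`, `session`, `task_id`, `time_s` (blank
#' for DNF attempts), `dnf` (0/1), `quadrant` (1-4).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_session_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = "c", session = "i", task_id = "c", time_s = "d",
    dnf = "i", quadrant = "i"))
}

#' Read a BBT trial log CSV
#'
#' Columns: `subject_id`, `session`, `trial`, `blocks`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_bbt_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = "c", session = "i", trial = "i", blocks = "i"))
}

#' Validate pipeline inputs
#'
#' Checks the session log, BBT log and bounds table for schema and value
#' problems before analysis: required columns, nonnegative times, DNF rows
#' without times (and vice versa), quadrant codes in 1-4, every logged task
#' present in the bounds table, bounds ordering, and session contiguity per
#' subject. Findings are itemised rather than thrown, so a report can list
#' every problem at once.
#'
#' @param session_log Session-log tibble (see [read_session_log()]).
#' @param bbt Optional BBT tibble.
#' @param bounds Normative-bounds tibble.
#' @return A list with `pass` (logical) and `findings`, a tibble with
#'   columns `table`, `row`, `message` (zero rows when everything passes).
#' @export
validate_inputs <- function(session_log, bbt = NULL,
                            bounds = default_bounds()) {
  findings <- list()
  note <- function(table, row, message) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(table = table, row = row, message = message)
  }

  need <- c("subject_id", "session", "task_id", "time_s", "dnf", "quadrant")
  miss <- setdiff(need, names(session_log))
  if (length(miss)) {
    note("session_log", NA_integer_,
         paste("missing column(s):", paste(miss, collapse = ", ")))
  } else {
    bad <- which(!(session_log$quadrant %in% 1:4))
    for (r in bad) note("session_log", r, paste0("quadrant ",
      session_log$quadrant[r], " outside 1..4"))
    bad <- which(!is.na(session_log$time_s) & session_log$time_s < 0)
    for (r in bad) note("session_log", r, "negative time_s")
    bad <- which(session_log$dnf == 1 & !is.na(session_log$time_s))
    for (r in bad) note("session_log", r, "DNF attempt has a recorded time")
    bad <- which(session_log$dnf == 0 & is.na(session_log$time_s))
    for (r in bad) note("session_log", r, "non-DNF attempt missing time_s")
    unk <- setdiff(unique(session_log$task_id), bounds$task_id)
    for (u in unk) note("session_log", NA_integer_,
                        paste0("task '", u, "' missing from bounds table"))
    gaps <- session_log |>
      dplyr::distinct(.data$subject_id, .data$session) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(contiguous = all(diff(sort(.data$session)) == 1),
                       .groups = "drop")
    for (s in gaps$subject_id[!gaps$contiguous]) {
      note("session_log", NA_integer_,
           paste0("subject '", s, "' has non-contiguous sessions"))
    }
  }

  if (!is.null(bbt)) {
    miss <- setdiff(c("subject_id", "session", "trial", "blocks"),
                    names(bbt))
    if (length(miss)) {
      note("bbt", NA_integer_,
           paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      bad <- which(is.na(bbt$blocks) | bbt$blocks < 0)
      for (r in bad) note("bbt", r, "blocks must be a nonnegative count")
    }
  }

  bounds_err <- tryCatch({ validate_bounds(bounds); NULL },
                         error = function(e) conditionMessage(e))
  if (!is.null(bounds_err)) note("bounds", NA_integer_, bounds_err)

  findings <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(table = character(), row = integer(),
                   message = character())
  list(pass = nrow(findings) == 0, findings = findings)
}
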