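#' Normative task-time boundaries
#'
#' Each of the 22 timed tasks is scaled between a lower boundary `n_lower_s`
#' (the average normative completion time, scoring 100) and an upper boundary
#' `m_upper_s` (eight times the normative time, scoring 0). The packaged
#' default table is illustrative — plausible normative times chosen for
#' testing and simulation, not a published normative data set — and should be
#' replaced with study-specific bounds via [read_bounds()] for real analyses.
#'
#' @return A tibble with columns `task_id`, `n_lower_s`, `m_upper_s`.
#' @seealso [read_bounds()], [default_task_patterns()]
#' @export
#' @examples
#' default_bounds()
default_bounds <- function() {
  read_bounds(system.file("extdata", "normative_bounds_default.csv",
                          package = "bypasstrain"))
}

#' Default task-to-prehensile-pattern mapping
#'
#' Maps each task to the prehensile pattern(s) it exercises. The 12 abstract
#' tasks (light/heavy x six patterns) map by name; the 10 everyday tasks load
#' one or two patterns each so that the membership counts per pattern are
#' 3, 3, 6, 5, 5, 3 (spherical, tripod, power, lateral, tip, extension),
#' summing to 25 — the counts used to weight the summary index. The everyday
#' task assignments are a documented, overridable convention.
#'
#' @return A tibble with columns `task_id`, `pattern`; one row per
#'   task-pattern membership (25 rows for the default 22-task battery).
#' @export
default_task_patterns <- function() {
  tbl <- readr::read_csv(
    system.file("extdata", "task_patterns_default.csv",
                package = "bypasstrain"),
    col_types = readr::cols(task_id = "c", pattern = "c"))
  validate_task_patterns(tbl)
  tbl
}

#' Prehensile-pattern weights for the summary index
#'
#' Weights for combining the six pattern indexes (LIF) into the weighted
#' summary index (wLIF): each pattern is weighted by its number of member
#' tasks and the total is divided by the grand membership count. With the
#' default mapping the weights are 3, 3, 6, 5, 5, 3 over a divisor of 25.
#'
#' @param task_patterns Task-to-pattern mapping tibble
#'   (see [default_task_patterns()]).
#' @return A named numeric vector of integer weights, one per pattern, in
#'   canonical pattern order. The divisor is `sum()` of the vector.
#' @export
#' @examples
#' pattern_weights()
pattern_weights <- function(task_patterns = default_task_patterns()) {
  counts <- table(factor(task_patterns$pattern, levels = pattern_levels))
  if (any(counts == 0)) {
    stop("task-pattern mapping leaves pattern(s) empty: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  setNames(as.numeric(counts), names(counts))
}

#' Read a normative-bounds table
#'
#' @param path CSV file with columns `task_id`, `n_lower_s`, `m_upper_s`.
#' @return A validated tibble.
#' @export
read_bounds <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    task_id = "c", n_lower_s = "d", m_upper_s = "d"))
  validate_bounds(tbl)
  tbl
}

validate_bounds <- function(bounds) {
  stopifnot(all(c("task_id", "n_lower_s", "m_upper_s") %in% names(bounds)))
  if (anyDuplicated(bounds$task_id)) {
    stop("duplicate task_id in bounds table", call. = FALSE)
  }
  bad <- !(bounds$n_lower_s > 0 & bounds$n_lower_s < bounds$m_upper_s)
  if (any(bad)) {
    stop("bounds must satisfy 0 < n_lower_s < m_upper_s; violated for: ",
         paste(bounds$task_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(bounds)
}

validate_task_patterns <- function(task_patterns) {
  stopifnot(all(c("task_id", "pattern") %in% names(task_patterns)))
  unknown <- setdiff(unique(task_patterns$pattern), pattern_levels)
  if (length(unknown)) {
    stop("unknown prehensile pattern(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(task_patterns)
}

#' Published learning-curve fits for each scoring category
#'
#' Learning-plateau, learning-rate, and goodness-of-fit values reported for
#' every scoring category (22 task scores, 6 pattern indexes, the weighted
#' summary index, and the Box and Blocks Test) in a six-subject,
#' ten-session bypass-prosthesis training study, together with the reported
#' training endpoint for each. Shipped so the endpoint rule and summary
#' statistics can be validated against reported values without raw data.
#'
#' @return A tibble with columns `category`, `measure` (`ts`, `lif`, `wlif`,
#'   `bbt`), `plateau`, `rate`, `r2`, `endpoint`, `session_offset`.
#' @export
#' @examples
#' head(reference_fits())
reference_fits <- function() {
  readr::read_csv(
    system.file("extdata", "reference_fits.csv", package = "bypasstrain"),
    col_types = readr::cols(
      category = "c", measure = "c", plateau = "d", rate = "d",
      r2 = "d", endpoint = "i", session_offset = "i"))
}
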