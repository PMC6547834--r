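#' Configuration for a synthetic training cohort
#'
#' Defines the generative model for a simulated longitudinal training study:
#' `n_subjects` trainees completing `n_sessions` sessions, each subject's
#' summary-score trajectory following an inverse learning curve
#' `a_i - b_i / X` with subject-level parameter variation and per-session
#' Gaussian noise, task failures (DNF) whose probability decays
#' geometrically with training, three BBT trials per session from session 2,
#' and per-task orientation quadrants from a Markov switch process.
#'
#' The default population parameters (`pop_plateau` 79.75, `pop_rate` 22.09;
#' `bbt_plateau` 37.21, `bbt_rate` 15.91) are the fitted learning-curve
#' values reported for a six-subject, ten-session bypass-prosthesis training
#' cohort, so simulated cohorts emulate that study's conditions. Dispersion
#' defaults are chosen so the session-1 between-subject spread is near the
#' reported values (SD about 11.5 score units for the summary index, about
#' 4.5 blocks for the BBT).
#'
#' @param n_subjects Number of subjects (default 6, at least 2).
#' @param n_sessions Number of training sessions (default 10).
#' @param pop_plateau,pop_rate Population learning plateau and rate for the
#'   summary score (0-100 scale).
#' @param subject_sd_plateau,subject_sd_rate SDs of subject-level plateau
#'   and rate draws.
#' @param noise_sd SD of the per-session score noise.
#' @param task_jitter_sdlog Log-scale SD of the mean-one lognormal jitter
#'   applied to back-solved task times.
#' @param dnf_base_prob Session-1 probability that a task attempt fails.
#' @param dnf_decay Geometric per-session decay factor of the DNF
#'   probability.
#' @param bbt_plateau,bbt_rate Population BBT learning curve (blocks/min,
#'   administration index 1 = session 2).
#' @param bbt_subject_sd_plateau,bbt_subject_sd_rate SDs of subject-level
#'   BBT parameters.
#' @param bbt_noise_sd SD of per-trial BBT noise (blocks).
#' @param preposition_propensity Mean per-subject probability of switching
#'   quadrant between consecutive tasks.
#' @param preposition_sd SD of the subject-level propensity draws.
#' @param seed Integer RNG seed for full reproducibility, or `NULL`.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 6, n_sessions = 10,
                          pop_plateau = 79.75, pop_rate = 22.09,
                          subject_sd_plateau = 8, subject_sd_rate = 6,
                          noise_sd = 3, task_jitter_sdlog = 0.08,
                          dnf_base_prob = 0.15, dnf_decay = 0.5,
                          bbt_plateau = 37.21, bbt_rate = 15.91,
                          bbt_subject_sd_plateau = 3,
                          bbt_subject_sd_rate = 2, bbt_noise_sd = 2,
                          preposition_propensity = 0.3,
                          preposition_sd = 0.15, seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions),
              pop_plateau = pop_plateau, pop_rate = pop_rate,
              subject_sd_plateau = subject_sd_plateau,
              subject_sd_rate = subject_sd_rate, noise_sd = noise_sd,
              task_jitter_sdlog = task_jitter_sdlog,
              dnf_base_prob = dnf_base_prob, dnf_decay = dnf_decay,
              bbt_plateau = bbt_plateau, bbt_rate = bbt_rate,
              bbt_subject_sd_plateau = bbt_subject_sd_plateau,
              bbt_subject_sd_rate = bbt_subject_sd_rate,
              bbt_noise_sd = bbt_noise_sd,
              preposition_propensity = preposition_propensity,
              preposition_sd = preposition_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  sds <- c(cfg$subject_sd_plateau, cfg$subject_sd_rate, cfg$noise_sd,
           cfg$task_jitter_sdlog, cfg$bbt_subject_sd_plateau,
           cfg$bbt_subject_sd_rate, cfg$bbt_noise_sd, cfg$preposition_sd)
  if (any(sds < 0)) stop("dispersion parameters must be >= 0", call. = FALSE)
  probs <- c(cfg$dnf_base_prob, cfg$dnf_decay, cfg$preposition_propensity)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (cfg$n_sessions < 3) stop("need at least 3 sessions", call. = FALSE)
  if (cfg$pop_plateau <= 0 || cfg$bbt_plateau <= 0) {
    stop("population plateaus must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic training cohort
#'
#' Simulates the complete measurement record of a training study under the
#' generative model described in [cohort_config()]. Each subject's target
#' summary score at session `X` is `a_i - b_i / X` plus noise, clamped to
#' `[0, 100]`; per-task completion times are back-solved through the inverse
#' of the task-score scale (so re-scoring the log reproduces the target
#' score in expectation) and multiplied by mean-one lognormal jitter, which
#' keeps all times positive. DNF attempts carry no time but keep their
#' quadrant record. BBT trials run on sessions `2..n_sessions` with three
#' trials each, rounded to nonnegative integer block counts.
#'
#' @param config A [cohort_config()].
#' @param bounds Normative-bounds table used to back-solve times.
#' @return A list with tibbles `session_log` (`subject_id`, `session`,
#'   `task_id`, `time_s`, `dnf`, `quadrant`), `bbt` (`subject_id`,
#'   `session`, `trial`, `blocks`), the per-subject `subjects` parameters,
#'   and the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' head(cohort$session_log)
generate_cohort <- function(config = cohort_config(),
                            bounds = default_bounds()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_bounds(bounds)
  if (!is.null(config$seed)) set.seed(config$seed)

  ns <- config$n_subjects
  nx <- config$n_sessions
  tasks <- bounds$task_id
  nt <- length(tasks)

  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(ns)),
    a = pmin(pmax(rnorm(ns, config$pop_plateau, config$subject_sd_plateau),
                  1), 100),
    b = pmax(rnorm(ns, config$pop_rate, config$subject_sd_rate), 0),
    bbt_a = pmax(rnorm(ns, config$bbt_plateau,
                       config$bbt_subject_sd_plateau), 1),
    bbt_b = pmax(rnorm(ns, config$bbt_rate, config$bbt_subject_sd_rate), 0),
    propensity = pmin(pmax(rnorm(ns, config$preposition_propensity,
                                 config$preposition_sd), 0), 1))

  logs <- vector("list", ns * nx)
  bbts <- vector("list", ns * (nx - 1))
  li <- 0L; bi <- 0L
  for (i in seq_len(ns)) {
    for (x in seq_len(nx)) {
      target <- subjects$a[i] - subjects$b[i] / x +
        rnorm(1, 0, config$noise_sd)
      target <- min(max(target, 0), 100)
      # invert the linear score scale, then jitter multiplicatively
      t0 <- bounds$m_upper_s - target / 100 *
        (bounds$m_upper_s - bounds$n_lower_s)
      jit <- if (config$task_jitter_sdlog > 0) {
        rlnorm(nt, -config$task_jitter_sdlog^2 / 2, config$task_jitter_sdlog)
      } else {
        rep(1, nt)
      }
      times <- t0 * jit
      p_dnf <- config$dnf_base_prob * config$dnf_decay^(x - 1)
      dnf <- runif(nt) < p_dnf
      times[dnf] <- NA_real_

      quad <- integer(nt)
      quad[1] <- sample.int(4, 1)
      for (k in 2:nt) {
        quad[k] <- if (runif(1) < subjects$propensity[i]) {
          sample(setdiff(1:4, quad[k - 1]), 1)
        } else {
          quad[k - 1]
        }
      }

      li <- li + 1L
      logs[[li]] <- tibble::tibble(
        subject_id = subjects$subject_id[i], session = x, task_id = tasks,
        time_s = times, dnf = as.integer(dnf), quadrant = quad)

      if (x >= 2) {
        k <- x - 1
        mu <- subjects$bbt_a[i] - subjects$bbt_b[i] / k
        blocks <- pmax(0, round(mu + rnorm(3, 0, config$bbt_noise_sd)))
        bi <- bi + 1L
        bbts[[bi]] <- tibble::tibble(
          subject_id = subjects$subject_id[i], session = x, trial = 1:3,
          blocks = as.integer(blocks))
      }
    }
  }

  list(session_log = dplyr::bind_rows(logs), bbt = dplyr::bind_rows(bbts),
       subjects = subjects, config = config)
}

#' Write a synthetic cohort to CSV files with a manifest
#'
#' Emits the session-log and BBT CSVs in the dialect consumed by the
#' reading functions, plus a JSON manifest recording the generating
#' configuration (including the seed). The same configuration and seed
#' always produce byte-identical files.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(session_log = file.path(dir, "session_log.csv"),
             bbt = file.path(dir, "bbt_log.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(cohort$session_log, paths["session_log"])
  readr::write_csv(cohort$bbt, paths["bbt"])
  jsonlite::write_json(unclass(cohort$config), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Tiny deterministic worked fixture
#'
#' A hand-constructed dataset — 2 subjects, 3 sessions, 4 tasks (covering
#' all six prehensile patterns through the default multi-pattern mapping),
#' BBT trials on sessions 2-3, and one DNF — whose scores are verifiable by
#' hand. Task times are chosen so each subject's tasks score a common round
#' value per session (subject S01: 40, 60, 70; S02: 50, 70, 80), except the
#' session-1 DNF of S01 which zeroes the tripod pattern and gives
#' wlif = (3*40 + 3*0 + 6*40 + 5*40 + 5*40 + 3*40) / 25 = 35.2. The
#' session-2 effect size is then mean(24.8, 20) / sd(24.8, 20)
#' = 22.4 / (2.4 * sqrt(2)) = 14 * sqrt(2) / 3.
#'
#' The same tables are shipped as plain CSV under `inst/extdata/` (files
#' `worked_*.csv`) together with the expected scoring output.
#'
#' @return A list with tibbles `session_log`, `bbt`, and the subset of
#'   [default_bounds()] covering the fixture's tasks.
#' @export
generate_worked_fixture <- function() {
  tasks <- c("lifting_light_object", "rotate_screw", "door_handle",
             "open_close_zip")
  bounds <- default_bounds()
  bounds <- bounds[bounds$task_id %in% tasks, ]
  # time for target score s on task with bounds (n, m): m - s/100 * (m - n)
  time_for <- function(s) {
    idx <- match(tasks, bounds$task_id)
    bounds$m_upper_s[idx] - s / 100 *
      (bounds$m_upper_s[idx] - bounds$n_lower_s[idx])
  }
  targets <- list(S01 = c(40, 60, 70), S02 = c(50, 70, 80))
  quads <- list(c(1L, 1L, 2L, 2L), c(3L, 3L, 3L, 3L), c(1L, 2L, 1L, 2L),
                c(4L, 4L, 4L, 1L), c(2L, 2L, 2L, 2L), c(1L, 3L, 3L, 4L))
  rows <- list(); qi <- 0L
  for (subj in names(targets)) {
    for (ses in 1:3) {
      qi <- qi + 1L
      times <- time_for(targets[[subj]][ses])
      dnf <- rep(0L, 4)
      if (subj == "S01" && ses == 1) {           # the one DNF: rotate_screw
        dnf[tasks == "rotate_screw"] <- 1L
        times[tasks == "rotate_screw"] <- NA_real_
      }
      rows[[qi]] <- tibble::tibble(subject_id = subj, session = ses,
                                   task_id = tasks, time_s = times,
                                   dnf = dnf, quadrant = quads[[qi]])
    }
  }
  bbt <- tibble::tibble(
    subject_id = rep(c("S01", "S02"), each = 6),
    session = rep(rep(2:3, each = 3), 2),
    trial = rep(1:3, 4),
    blocks = c(20L, 22L, 24L, 30L, 30L, 30L, 25L, 26L, 27L, 33L, 35L, 34L))
  list(session_log = dplyr::bind_rows(rows), bbt = bbt, bounds = bounds)
}
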