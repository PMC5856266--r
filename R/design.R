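#' Condition vocabulary
#'
#' The task is modelled with nine conditions: four rule-discovery conditions
#' of interest crossing domain (verbal, spatial) with search type (separate,
#' parallel), two confirmation conditions, two working-memory control
#' conditions, and one error condition collecting absent or incorrect
#' discoveries.
#'
#' @return A tibble with one row per condition: `condition`, `phase`
#'   (discovery, confirmation, control, error), `domain`, `search`
#'   (`NA` outside the conditions of interest) and `of_interest`.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  tibble(
    condition = c("disc_verbal_separate", "disc_spatial_separate",
                  "disc_verbal_parallel", "disc_spatial_parallel",
                  "conf_verbal", "conf_spatial",
                  "ctrl_verbal", "ctrl_spatial",
                  "error"),
    phase = c(rep("discovery", 4), rep("confirmation", 2),
              rep("control", 2), "error"),
    domain = c("verbal", "spatial", "verbal", "spatial",
               "verbal", "spatial", "verbal", "spatial", NA),
    search = c("separate", "separate", "parallel", "parallel",
               NA, NA, NA, NA, NA),
    of_interest = c(rep(TRUE, 4), rep(FALSE, 5))
  )
}

conditions_of_interest <- function() {
  condition_table()$condition[condition_table()$of_interest]
}

#' Experiment design parameters
#'
#' Parameters of the simulated two-session rule-discovery experiment:
#' 13 subjects, 2 sessions, 4 runs per session, epochs whose duration
#' averages 17 s in session 1 and 10 s in session 2, separated by blank
#' gaps jittered between 2 and 8 s on a 250 ms grid.
#'
#' @param n_subjects,n_sessions,n_runs Counts (defaults 13, 2, 4).
#' @param tr Repetition time in seconds (default 2).
#' @param mean_epoch_duration Mean epoch duration per session, seconds
#'   (default `c(17, 10)`, one value per session).
#' @param blank_range Range of inter-epoch blanks in seconds (default 2-8).
#' @param blank_step Jitter grid step in seconds (default 0.25).
#' @param epochs_per_condition_per_run Epochs per rule-discovery condition
#'   per run (default 1). Confirmation and control conditions get the same
#'   number of epochs per run.
#' @param errors_per_session Error-condition epochs per session (default 1),
#'   placed in a randomly chosen run, so some runs carry no error epoch.
#' @param duration_jitter Epoch durations are drawn uniformly within
#'   `mean * (1 +/- duration_jitter)` (default 0.3).
#' @return A `design_params` list.
#' @export
design_params <- function(n_subjects = 13, n_sessions = 2, n_runs = 4,
                          tr = 2.0,
                          mean_epoch_duration = c(17, 10),
                          blank_range = c(2, 8), blank_step = 0.25,
                          epochs_per_condition_per_run = 1,
                          errors_per_session = 1,
                          duration_jitter = 0.3) {
  check_count(n_subjects, "n_subjects")
  check_count(n_sessions, "n_sessions")
  check_count(n_runs, "n_runs")
  check_positive(tr, "tr")
  if (length(mean_epoch_duration) == 1) {
    mean_epoch_duration <- rep(mean_epoch_duration, n_sessions)
  } else if (length(mean_epoch_duration) > n_sessions) {
    mean_epoch_duration <- mean_epoch_duration[seq_len(n_sessions)]
  }
  if (length(mean_epoch_duration) != n_sessions) {
    stop_invalid("`mean_epoch_duration` needs one value per session.")
  }
  check_positive(mean_epoch_duration, "mean_epoch_duration")
  check_positive(blank_step, "blank_step")
  if (length(blank_range) != 2 || blank_range[1] > blank_range[2] ||
      any(blank_range < 0)) {
    stop_invalid("`blank_range` must be an increasing pair of non-negative seconds.")
  }
  check_count(epochs_per_condition_per_run, "epochs_per_condition_per_run")
  check_count(errors_per_session, "errors_per_session", min = 0)
  if (duration_jitter < 0 || duration_jitter >= 1) {
    stop_invalid("`duration_jitter` must lie in [0, 1).")
  }
  structure(
    list(n_subjects = n_subjects, n_sessions = n_sessions, n_runs = n_runs,
         tr = tr, mean_epoch_duration = mean_epoch_duration,
         blank_range = blank_range, blank_step = blank_step,
         epochs_per_condition_per_run = epochs_per_condition_per_run,
         errors_per_session = errors_per_session,
         duration_jitter = duration_jitter),
    class = "design_params"
  )
}

blank_grid <- function(params) {
  seq(params$blank_range[1], params$blank_range[2], by = params$blank_step)
}

#' Generate an experiment design
#'
#' Lays out, for every subject, session and run, an ordered sequence of
#' non-overlapping epochs separated by jittered blanks. Every run contains
#' every rule-discovery condition of interest (required for leave-one-run-out
#' cross-validation) together with confirmation and control epochs; error
#' epochs occur at low frequency and may be absent from most runs.
#'
#' @param params A [design_params()] object.
#' @param seed Integer seed; the design is deterministic given
#'   `(params, seed)`.
#' @return An `experiment_design` tibble with columns `subject`, `session`,
#'   `run`, `condition`, `domain`, `search`, `onset`, `duration` (seconds,
#'   onsets relative to run start).
#' @export
#' @examples
#' d <- generate_design(design_params(n_subjects = 2), seed = 1)
#' dplyr::count(d, subject, session, run)
generate_design <- function(params = design_params(), seed = 1) {
  if (!inherits(params, "design_params")) {
    params <- do.call(design_params, params)
  }
  conds <- condition_table()
  grid <- blank_grid(params)
  per_run_conds <- c(
    rep(conds$condition[conds$phase == "discovery"],
        params$epochs_per_condition_per_run),
    rep(conds$condition[conds$phase %in% c("confirmation", "control")],
        params$epochs_per_condition_per_run)
  )

  rows <- with_seed(derive_seed(seed, 101L), {
    out <- vector("list", params$n_subjects * params$n_sessions * params$n_runs)
    i <- 0L
    for (subj in seq_len(params$n_subjects)) {
      for (sess in seq_len(params$n_sessions)) {
        error_run <- if (params$errors_per_session > 0) {
          sample.int(params$n_runs, params$errors_per_session, replace = TRUE)
        } else integer(0)
        for (run in seq_len(params$n_runs)) {
          cs <- c(per_run_conds, rep("error", sum(error_run == run)))
          cs <- sample(cs)
          mu <- params$mean_epoch_duration[sess]
          dur <- stats::runif(length(cs),
                              mu * (1 - params$duration_jitter),
                              mu * (1 + params$duration_jitter))
          blanks <- sample(grid, length(cs), replace = TRUE)
          onset <- cumsum(blanks) + cumsum(c(0, dur[-length(dur)]))
          i <- i + 1L
          out[[i]] <- tibble(subject = subj, session = sess, run = run,
                             condition = cs, onset = onset, duration = dur)
        }
      }
    }
    dplyr::bind_rows(out)
  })

  rows <- dplyr::left_join(rows, conds[, c("condition", "domain", "search")],
                           by = "condition")
  rows <- rows[, c("subject", "session", "run", "condition", "domain",
                   "search", "onset", "duration")]
  structure(rows, class = c("experiment_design", class(tibble())),
            params = params, seed = seed)
}

#' Run durations implied by a design
#'
#' Number of scans needed per run: the last epoch offset plus the
#' haemodynamic tail (32 s), rounded up to whole TRs.
#'
#' @param design An `experiment_design` tibble (possibly filtered).
#' @param tr Repetition time, seconds.
#' @param hrf_tail Tail allowance in seconds (default 32).
#' @return Tibble with `subject`, `session`, `run`, `n_scans`.
#' @export
design_n_scans <- function(design, tr, hrf_tail = 32) {
  design |>
    dplyr::group_by(.data$subject, .data$session, .data$run) |>
    dplyr::summarise(
      n_scans = as.integer(ceiling((max(.data$onset + .data$duration) + hrf_tail) / tr)),
      .groups = "drop"
    )
}

#' Behavioral simulation parameters
#'
#' Cell means for exemplars-to-discovery follow the study conditions:
#' session means 2.1 (session 1) and 1.3 (session 2), with the spatial
#' domain and parallel search slightly harder. Values are generated as
#' `1 + (mean - 1) * m_s * e`, with a subject-level multiplier `m_s` and a
#' cell-level multiplier `e`, both mean-1 gamma variables, so every value
#' stays at or above one exemplar.
#'
#' @param n_subjects Count (default 13).
#' @param cell_means Tibble with columns `session`, `domain`, `search`,
#'   `mean`; defaults reproduce the session/domain/search margins above.
#' @param subject_cv,noise_cv Coefficients of variation of the subject and
#'   cell multipliers (defaults 0.25, 0.25); set both to 0 for deterministic
#'   cell means.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(n_subjects = 13,
                            cell_means = NULL,
                            subject_cv = 0.25, noise_cv = 0.25) {
  check_count(n_subjects, "n_subjects")
  if (is.null(cell_means)) {
    cell_means <- tibble(
      session = rep(1:2, each = 4),
      domain = rep(c("verbal", "verbal", "spatial", "spatial"), 2),
      search = rep(c("separate", "parallel"), 4),
      mean = c(1.85, 2.15, 2.05, 2.35,
               1.10, 1.20, 1.40, 1.50)
    )
  }
  if (any(cell_means$mean < 1)) {
    stop_invalid("behavioral cell means must be >= 1 exemplar.")
  }
  if (subject_cv < 0 || noise_cv < 0) {
    stop_invalid("coefficients of variation must be non-negative.")
  }
  structure(list(n_subjects = n_subjects, cell_means = cell_means,
                 subject_cv = subject_cv, noise_cv = noise_cv),
            class = "behavior_params")
}

#' Simulate exemplars-to-discovery behavior
#'
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @return A `behavior_table` tibble: `subject`, `session`, `domain`,
#'   `search`, `exemplars` (mean exemplars needed to discover the rule,
#'   always >= 1).
#' @export
#' @examples
#' b <- generate_behavior(behavior_params(), seed = 1)
#' dplyr::summarise(dplyr::group_by(b, session), mean(exemplars))
generate_behavior <- function(params = behavior_params(), seed = 1) {
  cells <- params$cell_means
  out <- with_seed(derive_seed(seed, 202L), {
    purrr::map_dfr(seq_len(params$n_subjects), function(subj) {
      m_s <- if (params$subject_cv > 0) {
        k <- 1 / params$subject_cv^2
        stats::rgamma(1, shape = k, rate = k)
      } else 1
      e <- if (params$noise_cv > 0) {
        k <- 1 / params$noise_cv^2
        stats::rgamma(nrow(cells), shape = k, rate = k)
      } else rep(1, nrow(cells))
      tibble(subject = subj, session = cells$session, domain = cells$domain,
             search = cells$search,
             exemplars = 1 + (cells$mean - 1) * m_s * e)
    })
  })
  structure(out, class = c("behavior_table", class(tibble())))
}
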