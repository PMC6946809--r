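#' Generate a trial schedule for the three learning problems
#'
#' Builds the full trial table for one participant: three problems, four
#' functional runs per problem, 32 trials per run (8 stimuli x 4 repetitions).
#' Trial order is pseudo-randomized in sub-blocks of 16 trials so that each
#' stimulus appears exactly twice per sub-block (hence exactly four times per
#' run). Event timing follows the task design: 3.5 s stimulus presentation, a
#' jittered 0.5-4.5 s fixation, 2 s feedback, and a jittered 2-6 s
#' inter-trial interval, with jitters drawn uniformly on a 0.5 s grid (the
#' 2-6 s window is the only inter-trial jitter compatible with 32 such trials
#' inside a 388 s run).
#'
#' The high-complexity problem can be constrained to come first (as in the
#' study, where low/medium order was then counterbalanced) or the order can
#' be supplied directly.
#'
#' @param bank A `problem_bank`.
#' @param problem_order Character vector permuting `c("low","medium","high")`.
#' @param seed Integer seed; schedules are bit-reproducible given a seed.
#' @param participant_id Identifier stored in the table.
#' @param run_length_s Run duration bound in seconds (default 388).
#' @param stim_duration_s,feedback_duration_s Event durations in seconds.
#' @return A `data.frame` (one row per trial) with columns `participant_id`,
#'   `problem`, `problem_order_idx`, `run`, `trial_index`, `stimulus_code`,
#'   `onset_s`, `stim_duration_s`, `feedback_onset_s`, `feedback_duration_s`,
#'   `true_class`, and empty `response`/`correct` columns to be filled by a
#'   learner.
#' @seealso [simulate_learner()] to fill in responses.
#' @export
make_trial_schedule <- function(bank, problem_order = c("high", "low", "medium"),
                                seed = 1L, participant_id = "sub-01",
                                run_length_s = 388, stim_duration_s = 3.5,
                                feedback_duration_s = 2) {
  stopifnot(setequal(problem_order, problem_levels()), length(problem_order) == 3L)
  with_seed(seed, {
    rows <- vector("list", 12L)
    i <- 0L
    for (p_idx in seq_along(problem_order)) {
      problem <- problem_order[p_idx]
      for (run in 1:4) {
        codes <- c(
          sample(rep(bank$class_map$code, 2L)),
          sample(rep(bank$class_map$code, 2L))
        )
        timing <- schedule_run_timing(
          n_trials = 32L, run_length_s = run_length_s,
          stim_duration_s = stim_duration_s,
          feedback_duration_s = feedback_duration_s
        )
        i <- i + 1L
        rows[[i]] <- data.frame(
          participant_id = participant_id,
          problem = problem,
          problem_order_idx = p_idx,
          run = run,
          trial_index = 1:32,
          stimulus_code = codes,
          onset_s = timing$onset,
          stim_duration_s = stim_duration_s,
          feedback_onset_s = timing$feedback_onset,
          feedback_duration_s = feedback_duration_s,
          true_class = stimulus_class(bank, codes, problem),
          response = NA_character_,
          correct = NA,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

# Draw jittered onsets for one run. Trial layout: stimulus (3.5 s), fixation
# jitter U{0.5, 1.0, ..., 4.5}, feedback (2 s), ITI jitter U{2, 2.5, ..., 6}.
schedule_run_timing <- function(n_trials, run_length_s, stim_duration_s,
                                feedback_duration_s, max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    fix_jit <- sample(seq(0.5, 4.5, by = 0.5), n_trials, replace = TRUE)
    iti_jit <- sample(seq(2, 6, by = 0.5), n_trials, replace = TRUE)
    trial_len <- stim_duration_s + fix_jit + feedback_duration_s + iti_jit
    onset <- c(0, cumsum(trial_len))[seq_len(n_trials)]
    end <- onset[n_trials] + stim_duration_s + fix_jit[n_trials] +
      feedback_duration_s
    if (end <= run_length_s) {
      return(list(
        onset = onset,
        feedback_onset = onset + stim_duration_s + fix_jit
      ))
    }
  }
  stop("could not fit ", n_trials, " trials into a ", run_length_s,
       " s run after ", max_tries, " attempts")
}
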