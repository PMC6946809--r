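#' SUSTAIN model parameters
#'
#' The supervised SUSTAIN category-learning model has five free parameters:
#' an attentional-focus exponent `gamma` controlling how sharply attention
#' tunings weight each attribute's receptive field, a lateral-inhibition
#' exponent `beta_inh` governing cluster competition, a learning rate `eta`,
#' a decision-consistency parameter `d` scaling the choice softmax, and a
#' cluster-recruitment activation threshold `tau_h`. Defaults are the
#' group-mean values estimated from behavior in the three-problem concept
#' learning task (gamma 8.96, beta 1.51, eta 0.08, d 17.04, tau_h 0.11).
#'
#' @param gamma Attentional-focus exponent, >= 0.
#' @param beta_inh Cluster-competition exponent, >= 0.
#' @param eta Learning rate in `[0, 1]`.
#' @param d Decision consistency, >= 0.
#' @param tau_h Recruitment activation threshold in `[0, 1]`.
#' @return A `sustain_params` list.
#' @export
sustain_params <- function(gamma = 8.96, beta_inh = 1.51, eta = 0.08,
                           d = 17.04, tau_h = 0.11) {
  p <- list(gamma = gamma, beta_inh = beta_inh, eta = eta, d = d,
            tau_h = tau_h)
  validate_sustain_params(p)
  structure(p, class = "sustain_params")
}

validate_sustain_params <- function(p) {
  vals <- unlist(p[c("gamma", "beta_inh", "eta", "d", "tau_h")])
  if (length(vals) != 5L || anyNA(vals)) {
    stop("sustain_params requires the five parameters gamma, beta_inh, eta, d, tau_h")
  }
  if (any(vals < 0) || p$eta > 1 || p$tau_h > 1) {
    stop("sustain_params out of bounds: all >= 0, eta and tau_h <= 1")
  }
  invisible(p)
}

#' Default fitting bounds for the five SUSTAIN parameters
#'
#' Wide boxes covering the group-mean estimates with margin.
#' @return A list with `lower` and `upper` named numeric vectors.
#' @export
sustain_bounds <- function() {
  list(
    lower = c(gamma = 0, beta_inh = 0, eta = 0, d = 0, tau_h = 0),
    upper = c(gamma = 20, beta_inh = 20, eta = 1, d = 30, tau_h = 1)
  )
}

#' Encode a stimulus code as per-attribute one-hot representation
#'
#' @param code A 3-character string of 0/1 bits (e.g. `"101"`).
#' @return A 3 x 2 matrix; row i is the one-hot encoding of attribute i over
#'   its two values (value 0, value 1).
#' @examples
#' encode_stimulus("000")  # rows all (1, 0)
#' @export
encode_stimulus <- function(code) {
  bits <- code_to_bits(code)
  t(vapply(bits, function(b) if (b == 0L) c(1, 0) else c(0, 1), numeric(2L)))
}

code_to_bits <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L ||
      grepl("[^01]", code)) {
    stop("stimulus code must be a 3-character string of 0s and 1s")
  }
  as.integer(strsplit(code, "")[[1L]])
}

#' Fresh SUSTAIN state: no clusters, equal attention tunings
#'
#' @param n_attr Number of stimulus attributes (3).
#' @return A `sustain_state` list with empty `clusters` and `lambdas = 1`.
#' @export
new_sustain_state <- function(n_attr = 3L) {
  structure(
    list(clusters = list(), lambdas = rep(1, n_attr)),
    class = "sustain_state"
  )
}

#' Receptive-field activation of each cluster for a stimulus
#'
#' Activation of cluster j is
#' `sum_i lambda_i^gamma exp(-lambda_i mu_ij) / sum_i lambda_i^gamma`,
#' where `mu_ij` is the halved city-block distance between the stimulus and
#' the cluster position on attribute i. A cluster exactly at the stimulus has
#' activation 1 regardless of the tunings.
#'
#' @param state A `sustain_state` with at least the `lambdas` field.
#' @param stim A 3 x 2 one-hot representation from [encode_stimulus()].
#' @param gamma Attentional-focus exponent.
#' @return Numeric vector of activations in `(0, 1]`, one per cluster
#'   (length 0 if the state has no clusters).
#' @export
cluster_activation <- function(state, stim, gamma) {
  if (length(state$clusters) == 0L) return(numeric(0L))
  lam <- state$lambdas
  lam_pow <- lam^gamma
  denom <- sum(lam_pow)
  vapply(state$clusters, function(cl) {
    mu <- 0.5 * rowSums(abs(cl$position - stim))
    if (denom > 0) sum(lam_pow * exp(-lam * mu)) / denom else 0
  }, numeric(1L))
}

# Winner-take-all competition: the winner's output after lateral inhibition,
# plus its category-unit activations. Ties break to the most recently
# recruited cluster, so a fresh cluster displaces a stale duplicate at the
# same position (critical under problem-to-problem state carryover).
cluster_competition <- function(state, act, beta_inh) {
  winner <- length(act) + 1L - which.max(rev(act))
  inhib <- sum(act^beta_inh)
  out <- if (inhib > 0) (act[winner]^beta_inh / inhib) * act[winner] else 0
  list(winner = winner, output = out,
       category = state$clusters[[winner]]$weights * out)
}

#' Choice probabilities over the two categories
#'
#' Softmax with consistency `d` over the winning cluster's category-unit
#' activations. With no clusters (or `d = 0`) the model responds at chance.
#'
#' @inheritParams cluster_activation
#' @param params A [sustain_params()] object.
#' @return Named numeric vector `c(A = , B = )` summing to 1.
#' @export
choice_probabilities <- function(state, stim, params) {
  act <- cluster_activation(state, stim, params$gamma)
  if (length(act) == 0L) return(c(A = 0.5, B = 0.5))
  comp <- cluster_competition(state, act, params$beta_inh)
  e <- exp(params$d * comp$category)
  p <- e / sum(e)
  names(p) <- c("A", "B")
  p
}

#' One supervised learning step
#'
#' Recruits a new cluster centered on the stimulus when the state is empty,
#' when the winning cluster predicts the wrong category, or when the winner's
#' activation falls below `tau_h`. Otherwise (and also after recruitment,
#' applied to the fresh winner) the winner moves toward the stimulus at rate
#' `eta`, its association weights follow a humble-teacher (+/-1) delta rule,
#' and each attention tuning `lambda_i` takes a receptive-field gradient step
#' `eta * exp(-lambda_i mu_i) * (1 - lambda_i mu_i)`, clamped at 0.
#'
#' @inheritParams choice_probabilities
#' @param true_class `"A"` or `"B"` (the feedback).
#' @return List with the updated `state` and logical `recruited`.
#' @export
learn_trial <- function(state, stim, true_class, params) {
  truth <- match(true_class, c("A", "B"))
  if (is.na(truth)) stop("true_class must be 'A' or 'B'")
  act <- cluster_activation(state, stim, params$gamma)

  recruit <- FALSE
  if (length(act) == 0L) {
    recruit <- TRUE
  } else {
    comp <- cluster_competition(state, act, params$beta_inh)
    predicted <- if (comp$category[1L] >= comp$category[2L]) 1L else 2L
    recruit <- (predicted != truth) || (act[comp$winner] < params$tau_h)
  }

  if (recruit) {
    state$clusters[[length(state$clusters) + 1L]] <-
      list(position = stim, weights = c(0, 0))
    winner <- length(state$clusters)
    act <- c(act, 1)
    inhib <- sum(act^params$beta_inh)
    out <- 1 / inhib
    category <- c(0, 0)
  } else {
    winner <- comp$winner
    out <- comp$output
    category <- comp$category
  }

  cl <- state$clusters[[winner]]
  mu <- 0.5 * rowSums(abs(cl$position - stim))
  lam <- state$lambdas
  state$lambdas <- pmax(0, lam + params$eta * exp(-lam * mu) * (1 - lam * mu))
  cl$position <- cl$position + params$eta * (stim - cl$position)
  target <- ifelse(seq_len(2L) == truth, pmax(category, 1), pmin(category, -1))
  cl$weights <- cl$weights + params$eta * (target - category) * out
  state$clusters[[winner]] <- cl

  list(state = state, recruited = recruit)
}

#' Run SUSTAIN over an ordered trial sequence (reference implementation)
#'
#' Pure-R loop over [choice_probabilities()] and [learn_trial()]; the fast
#' C++ path used by [negative_log_likelihood()], [simulate_learner()] and
#' [fit_sustain()] is tested for trace-level equality against this function.
#'
#' @param codes Character vector of 3-bit stimulus codes in experienced order.
#' @param true_classes Character vector of `"A"`/`"B"` feedback labels.
#' @param params A [sustain_params()] object.
#' @param responses Optional observed responses (`"A"`/`"B"`/`NA`).
#' @return List with per-trial `p_a`, `p_resp`, `lambda` (trial x 3 matrix of
#'   post-update tunings), `recruited`, `n_clusters`, and the final `state`.
#' @export
sustain_run_reference <- function(codes, true_classes, params,
                                  responses = NULL) {
  n <- length(codes)
  state <- new_sustain_state()
  p_a <- p_resp <- numeric(n)
  recruited <- logical(n)
  n_clusters <- integer(n)
  lambda <- matrix(NA_real_, n, 3L)
  for (t in seq_len(n)) {
    stim <- encode_stimulus(codes[t])
    p <- choice_probabilities(state, stim, params)
    p_a[t] <- p[["A"]]
    p_resp[t] <- if (is.null(responses) || is.na(responses[t])) NA_real_
      else if (responses[t] == "A") p[["A"]] else p[["B"]]
    step <- learn_trial(state, stim, true_classes[t], params)
    state <- step$state
    recruited[t] <- step$recruited
    n_clusters[t] <- length(state$clusters)
    lambda[t, ] <- state$lambdas
  }
  list(p_a = p_a, p_resp = p_resp, lambda = lambda, recruited = recruited,
       n_clusters = n_clusters, state = state)
}

# Run the C++ core over an ordered trial table. mode "replay" learns from
# feedback and scores the observed responses; mode "simulate" samples
# responses from the choice rule (driven by R's RNG).
sustain_core <- function(trials, params, mode = c("replay", "simulate")) {
  mode <- match.arg(mode)
  bits <- do.call(rbind, lapply(strsplit(trials$stimulus_code, ""), as.integer))
  truth <- match(trials$true_class, c("A", "B")) - 1L
  if (anyNA(truth)) stop("true_class must be 'A' or 'B' on every trial")
  resp <- if (mode == "replay") {
    match(trials$response, c("A", "B")) - 1L
  } else {
    rep(NA_integer_, nrow(trials))
  }
  .sustain_core_cpp(bits, truth, resp, params$gamma, params$beta_inh,
                    params$eta, params$d, params$tau_h,
                    if (mode == "simulate") 1L else 0L)
}

# Order trials as the participant experienced them; error on ambiguity.
order_trials <- function(trials) {
  ord <- order(trials$problem_order_idx, trials$run, trials$trial_index)
  if (!identical(ord, seq_len(nrow(trials)))) {
    trials <- trials[ord, , drop = FALSE]
    rownames(trials) <- NULL
  }
  trials
}

assert_experienced_order <- function(trials) {
  ord <- order(trials$problem_order_idx, trials$run, trials$trial_index)
  if (!identical(ord, seq_len(nrow(trials)))) {
    stop("trials must be ordered as experienced ",
         "(problem_order_idx, run, trial_index)")
  }
  invisible(trials)
}

#' Simulate learner behavior on a schedule
#'
#' Fills the `response` and `correct` columns of a trial schedule by sampling
#' responses from SUSTAIN's choice rule while the model learns from the
#' feedback. Model state carries over between problems in the participant's
#' problem order, as in the fitting protocol.
#'
#' @param schedule Trial table from [make_trial_schedule()].
#' @param params A [sustain_params()] object.
#' @param seed Integer seed.
#' @return The schedule with `response`, `correct` filled and per-trial
#'   attention tunings `lambda1..lambda3` appended.
#' @export
simulate_learner <- function(schedule, params, seed = 1L) {
  validate_sustain_params(params)
  schedule <- order_trials(schedule)
  res <- with_seed(seed, sustain_core(schedule, params, mode = "simulate"))
  schedule$response <- c("A", "B")[res$response + 1L]
  schedule$correct <- schedule$response == schedule$true_class
  schedule$lambda1 <- res$lambda[, 1L]
  schedule$lambda2 <- res$lambda[, 2L]
  schedule$lambda3 <- res$lambda[, 3L]
  schedule
}

#' Negative log-likelihood of observed responses under SUSTAIN
#'
#' Replays the participant's experienced trial order (all problems in
#' sequence, state carrying over), accumulating `-log P(response)` over
#' responded trials. A floor of 1e-6 per trial keeps the likelihood finite.
#'
#' @param params A [sustain_params()] object (or named numeric of the five
#'   parameters in order gamma, beta_inh, eta, d, tau_h).
#' @param trials Trial table with filled `response`, ordered as experienced.
#' @param floor Per-trial probability floor.
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, trials, floor = 1e-6) {
  if (!inherits(params, "sustain_params")) {
    params <- sustain_params(params[[1L]], params[[2L]], params[[3L]],
                             params[[4L]], params[[5L]])
  }
  assert_experienced_order(trials)
  res <- sustain_core(trials, params, mode = "replay")
  -sum(log(pmax(res$p_resp, floor)), na.rm = TRUE)
}

#' Extract the attention-tuning trajectory at fixed parameters
#'
#' Replays the experienced trial order with parameters held fixed and records
#' the attention tunings `lambda_i` on each trial (state after that trial's
#' feedback update).
#'
#' @inheritParams negative_log_likelihood
#' @return Data frame with `problem`, `run`, `trial_index`, `block` (the run
#'   index within problem) and `lambda1..lambda3`.
#' @export
attention_trajectory <- function(params, trials) {
  assert_experienced_order(trials)
  res <- sustain_core(trials, params, mode = "replay")
  data.frame(
    participant_id = trials$participant_id,
    problem = trials$problem,
    run = trials$run,
    block = trials$run,
    trial_index = trials$trial_index,
    lambda1 = res$lambda[, 1L],
    lambda2 = res$lambda[, 2L],
    lambda3 = res$lambda[, 3L],
    stringsAsFactors = FALSE
  )
}

#' Fit SUSTAIN to one participant's trial-by-trial behavior
#'
#' Maximum-likelihood estimation of the five parameters by differential
#' evolution over box bounds, replaying the participant's experienced trial
#' order with state carryover across problems. After optimization the
#' attention trajectory is extracted at the best-fitting parameters.
#'
#' @param trials Trial table with responses, ordered as experienced.
#' @param bounds List with `lower`/`upper` as in [sustain_bounds()].
#' @param seed Integer seed for the optimizer.
#' @param control Optional list passed to [de_optimize()] (`pop_size`,
#'   `max_gen`, `F`, `CR`, `reltol`).
#' @return A `sustain_fit` list: `params`, `nll`, `p_resp` (per-trial choice
#'   probabilities of the observed responses), `attention` (trajectory data
#'   frame), and `optimizer` metadata (seed, generations, convergence flag).
#' @export
fit_sustain <- function(trials, bounds = sustain_bounds(), seed = 1L,
                        control = list()) {
  assert_experienced_order(trials)
  fn <- function(x) {
    p <- sustain_params(x[1L], x[2L], x[3L], x[4L], x[5L])
    negative_log_likelihood(p, trials)
  }
  opt <- do.call(de_optimize, c(
    list(fn = fn, lower = bounds$lower, upper = bounds$upper, seed = seed),
    control
  ))
  best <- sustain_params(opt$par[1L], opt$par[2L], opt$par[3L], opt$par[4L],
                         opt$par[5L])
  res <- sustain_core(trials, best, mode = "replay")
  structure(
    list(
      params = best,
      nll = opt$value,
      p_resp = res$p_resp,
      attention = attention_trajectory(best, trials),
      optimizer = list(seed = seed, generations = opt$generations,
                       converged = opt$converged, n_eval = opt$n_eval)
    ),
    class = "sustain_fit"
  )
}

#' @export
print.sustain_fit <- function(x, ...) {
  cat("SUSTAIN fit: NLL =", format(x$nll, digits = 6), "over",
      sum(!is.na(x$p_resp)), "responded trials\n")
  cat(sprintf("  gamma=%.3f beta=%.3f eta=%.4f d=%.2f tau_h=%.3f\n",
              x$params$gamma, x$params$beta_inh, x$params$eta, x$params$d,
              x$params$tau_h))
  cat("  optimizer: ", x$optimizer$generations, " generations, converged = ",
      x$optimizer$converged, "\n", sep = "")
  invisible(x)
}
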