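test_that("stimulus encoding is the per-attribute one-hot map", {
  expect_equal(encode_stimulus("000"),
               rbind(c(1, 0), c(1, 0), c(1, 0)), ignore_attr = TRUE)
  expect_equal(encode_stimulus("101"),
               rbind(c(0, 1), c(1, 0), c(0, 1)), ignore_attr = TRUE)
  codes <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  encs <- lapply(codes, encode_stimulus)
  expect_identical(anyDuplicated(encs), 0L)
  expect_error(encode_stimulus("01"), "3-character")
  expect_error(encode_stimulus("012"), "3-character")
})

test_that("receptive-field activation follows the halved city-block form", {
  state <- new_sustain_state()
  stim <- encode_stimulus("010")
  # cluster exactly at the stimulus: activation 1 for any lambda, gamma
  state$clusters <- list(list(position = stim, weights = c(0.3, -0.2)))
  for (lam in list(c(1, 1, 1), c(5, 0.2, 2))) {
    state$lambdas <- lam
    for (g in c(0.5, 1, 9)) {
      expect_equal(cluster_activation(state, stim, g), 1)
    }
  }
  # equal lambdas, one mismatching attribute: (2 + exp(-lambda)) / 3,
  # independent of gamma because the weights cancel
  other <- encode_stimulus("011")
  state$clusters <- list(list(position = other, weights = c(0, 0)))
  for (lam in c(0.5, 1, 3)) {
    state$lambdas <- rep(lam, 3)
    for (g in c(1, 4)) {
      expect_equal(cluster_activation(state, stim, g), (2 + exp(-lam)) / 3)
    }
  }
  # raising lambda on the mismatching attribute strictly lowers activation
  state$lambdas <- c(1, 1, 1)
  a1 <- cluster_activation(state, stim, 2)
  state$lambdas <- c(1, 1, 4)   # attribute 3 mismatches between 010 and 011
  a2 <- cluster_activation(state, stim, 2)
  expect_lt(a2, a1)
})

test_that("the choice rule is a consistency-scaled softmax with chance fallbacks", {
  state <- new_sustain_state()
  stim <- encode_stimulus("110")
  # no clusters -> chance
  expect_equal(choice_probabilities(state, stim, sustain_params()),
               c(A = 0.5, B = 0.5))
  # d = 0 -> chance regardless of state
  state$clusters <- list(list(position = encode_stimulus("000"),
                              weights = c(2, -1)))
  p0 <- sustain_params(d = 0)
  expect_equal(choice_probabilities(state, stim, p0), c(A = 0.5, B = 0.5))
  # single cluster with weights (1, 0): P(A) = exp(d o) / (exp(d o) + 1)
  params <- sustain_params(gamma = 2, beta_inh = 1.5, d = 3)
  state$clusters <- list(list(position = encode_stimulus("000"),
                              weights = c(1, 0)))
  act <- cluster_activation(state, stim, params$gamma)
  o <- act^(params$beta_inh + 1) / act^params$beta_inh  # single cluster
  expect_equal(unname(choice_probabilities(state, stim, params)["A"]),
               exp(params$d * o) / (exp(params$d * o) + 1))
  # probabilities always sum to 1
  for (code in c("000", "011", "101", "111")) {
    p <- choice_probabilities(state, encode_stimulus(code), params)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("learning recruits, updates the winner only, and keeps lambda non-negative", {
  params <- sustain_params()
  state <- new_sustain_state()
  stim <- encode_stimulus("101")
  # first trial ever recruits one cluster centered on the stimulus
  step <- learn_trial(state, stim, "A", params)
  expect_true(step$recruited)
  expect_length(step$state$clusters, 1L)
  # position has moved from the stimulus only by the (no-op) eta step
  expect_equal(step$state$clusters[[1]]$position, stim, ignore_attr = TRUE)
  # eta = 0 freezes positions and weights; only recruitment can change state
  p_frozen <- sustain_params(eta = 0)
  st <- step$state
  before <- st$clusters[[1]]
  step2 <- learn_trial(st, stim, "A", p_frozen)
  expect_false(step2$recruited)
  expect_equal(step2$state$clusters[[1]]$position, before$position)
  expect_equal(step2$state$clusters[[1]]$weights, before$weights)
  expect_equal(step2$state$lambdas, st$lambdas)
  # repeated supervised presentations make P(correct) non-decreasing
  st <- new_sustain_state()
  pc <- numeric(20)
  for (i in 1:20) {
    pc[i] <- choice_probabilities(st, stim, params)[["A"]]
    st <- learn_trial(st, stim, "A", params)$state
  }
  expect_true(all(diff(pc) >= -1e-12))
  expect_gt(pc[20], 0.9)
  expect_true(all(st$lambdas >= 0))
})

test_that("the C++ trial loop reproduces the pure-R reference exactly", {
  trials <- make_learner_trials(seed = 21)
  params <- sustain_params(gamma = 4.2, beta_inh = 2.1, eta = 0.15, d = 9,
                           tau_h = 0.3)
  sub <- trials[seq_len(160), ]
  ref <- sustain_run_reference(sub$stimulus_code, sub$true_class, params,
                               sub$response)
  cpp <- neurocompress:::sustain_core(sub, params, mode = "replay")
  expect_equal(cpp$p_a, ref$p_a, tolerance = 1e-12)
  expect_equal(cpp$p_resp, ref$p_resp, tolerance = 1e-12)
  expect_equal(cpp$lambda, ref$lambda, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(cpp$recruited, ref$recruited, ignore_attr = TRUE)
  expect_equal(cpp$n_clusters, ref$n_clusters, ignore_attr = TRUE)
  # cluster count never exceeds trial count
  expect_true(all(cpp$n_clusters <= seq_len(nrow(sub))))
})

test_that("the likelihood has its closed forms and ordering contracts", {
  trials <- make_learner_trials(seed = 31)
  # a d = 0 model emits every response with probability 1/2
  nll0 <- negative_log_likelihood(sustain_params(d = 0), trials)
  expect_equal(nll0, nrow(trials) * log(2), tolerance = 1e-10)
  # finite at the corners of the fitting box
  b <- sustain_bounds()
  for (x in list(b$lower, b$upper)) {
    expect_true(is.finite(negative_log_likelihood(
      sustain_params(x[1], x[2], x[3], x[4], x[5]), trials)))
  }
  # unordered trials are rejected
  shuffled <- trials[sample.int(nrow(trials)), ]
  expect_error(negative_log_likelihood(sustain_params(), shuffled),
               "ordered")
  # the generating parameters beat a distant parameter set on average
  gen <- sustain_params()
  distant <- sustain_params(gamma = 0.5, beta_inh = 10, eta = 0.9, d = 1,
                            tau_h = 0.9)
  diffs <- vapply(1:8, function(i) {
    tr <- make_learner_trials(seed = 300 + i)
    negative_log_likelihood(gen, tr) - negative_log_likelihood(distant, tr)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("simulated learners behave sensibly across parameter regimes", {
  bank <- make_problem_bank()
  sched <- make_trial_schedule(bank, seed = 41)
  # no learning, no consistency -> chance accuracy
  flat <- simulate_learner(sched, sustain_params(eta = 0, d = 0), seed = 1)
  expect_gt(mean(flat$correct), 0.4)
  expect_lt(mean(flat$correct), 0.6)
  # huge consistency after acquiring the unidimensional rule -> ceiling
  low <- sched[sched$problem == "low", ]
  sharp <- simulate_learner(low, sustain_params(d = 500), seed = 2)
  expect_equal(mean(sharp$correct[sharp$run == 4]), 1)
  # determinism under a fixed seed
  expect_identical(simulate_learner(sched, sustain_params(), seed = 9),
                   simulate_learner(sched, sustain_params(), seed = 9))
})

test_that("fresh-state learning speed is ordered by problem complexity", {
  # Monte-Carlo at the group-mean parameters: accuracy in the first two
  # runs of a problem learned from a fresh state is highest for the
  # unidimensional rule, then XOR, then parity.
  params <- sustain_params()
  acc <- matrix(NA_real_, 100, 3,
                dimnames = list(NULL, c("low", "medium", "high")))
  for (i in 1:100) {
    for (pr in colnames(acc)) {
      bank <- make_problem_bank(seed = i, randomize_feature_mapping = TRUE)
      ord <- c(pr, setdiff(c("low", "medium", "high"), pr))
      sched <- make_trial_schedule(bank, problem_order = ord, seed = i)
      first <- sched[sched$problem_order_idx == 1 & sched$run <= 2, ]
      tr <- simulate_learner(first, params, seed = 7000 + i)
      acc[i, pr] <- mean(tr$correct)
    }
  }
  m <- colMeans(acc)
  expect_gt(m["low"], m["medium"])
  expect_gt(m["medium"], m["high"])
})

test_that("trained attention concentrates on the relevant attribute", {
  params <- sustain_params()
  share <- vapply(1:100, function(i) {
    bank <- make_problem_bank(seed = 100 + i)
    sched <- make_trial_schedule(bank,
                                 problem_order = c("low", "medium", "high"),
                                 seed = i)
    tr <- simulate_learner(sched[sched$problem == "low", ], params,
                           seed = 500 + i)
    lam <- as.numeric(tr[nrow(tr), c("lambda1", "lambda2", "lambda3")])
    normalize_attention(lam)[1]
  }, numeric(1))
  # majority share on the relevant attribute in most runs; always above the
  # uniform share except for runs that solved the problem by pure
  # memorization (one cluster per stimulus leaves no attention gradient)
  expect_gte(mean(share > 0.5), 0.75)
  expect_gte(mean(share > 1 / 3), 0.90)
})

test_that("fitting is deterministic and beats the chance model", {
  trials <- make_learner_trials(seed = 51)
  sub <- trials[trials$problem_order_idx == 1, ]
  ctrl <- list(max_gen = 8L, pop_size = 20L)
  f1 <- fit_sustain(sub, seed = 5, control = ctrl)
  f2 <- fit_sustain(sub, seed = 5, control = ctrl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  # nested in the d = 0 (chance) model
  expect_lte(f1$nll, nrow(sub) * log(2))
  # the trajectory replays every trial
  expect_identical(nrow(f1$attention), nrow(sub))
  expect_true(all(as.matrix(f1$attention[, c("lambda1", "lambda2",
                                             "lambda3")]) >= 0))
})

test_that("parameter validation rejects out-of-bounds values", {
  expect_error(sustain_params(eta = 1.2), "bounds")
  expect_error(sustain_params(gamma = -1), "bounds")
  expect_error(sustain_params(tau_h = 2), "bounds")
})
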