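test_that("the double-gamma kernel is causal with a ~5 s peak", {
  h <- hrf_kernel(dt = 0.01)
  expect_identical(h[1], 0)
  expect_equal(max(h), 1)
  peak <- (which.max(h) - 1) * 0.01
  expect_lt(abs(peak - 5), 0.2)
  # refinement consistency: peak location stable to 0.1 s
  h2 <- hrf_kernel(dt = 0.1)
  expect_lt(abs((which.max(h2) - 1) * 0.1 - peak), 0.1 + 1e-9)
  expect_error(hrf_kernel(dt = 0), "positive")
  expect_error(hrf_kernel(peak_disp = -1), "positive")
})

test_that("LS-S designs isolate the target trial", {
  ev <- data.frame(
    onset_s = seq(10, by = 30, length.out = 8), stim_duration_s = 3.5,
    feedback_onset_s = seq(10, by = 30, length.out = 8) + 5,
    feedback_duration_s = 2, correct = rep(c(TRUE, FALSE), 4),
    response = rep(c("A", "B"), each = 4), trial_index = 1:8
  )
  motion <- matrix(rnorm(125 * 6), 125, 6)
  X <- build_design(ev, run_length_s = 250, TR = 2, target_trial = 3,
                    motion = motion)
  # trial/other split + 2 feedback + 2 response + 6 motion + intercept
  expect_identical(ncol(X), 13L)
  # causality: target regressor is (numerically) zero before the target
  # onset; the FFT convolution leaves only roundoff
  t_vol <- seq(0, by = 2, length.out = nrow(X))
  expect_lt(max(abs(X[t_vol < ev$onset_s[3], "target"])), 1e-10)
  # partition identity: different targets, same stimulus-regressor sum
  X5 <- build_design(ev, 250, 2, target_trial = 5, motion = motion)
  expect_equal(X[, "target"] + X[, "others"], X5[, "target"] + X5[, "others"])
  expect_error(build_design(ev, 250, 2, target_trial = 99), "not present")
  expect_error(build_design(ev, 100, 2, target_trial = 1), "beyond the")
})

test_that("noiseless LS-S recovers generating betas on sparse designs", {
  ev <- make_sparse_events(n_trials = 6, spacing = 40)
  rl <- 290
  set.seed(12)
  B <- matrix(rnorm(6 * 15), 6, 15)
  Y <- simulate_bold(ev, B, run_length_s = rl, TR = 2, noise_sd = 0,
                     nuisance_amp = 0, seed = 1)
  est <- lss_estimate(Y, ev, run_length_s = rl, TR = 2)
  expect_lt(max(abs(est - B)) / max(abs(B)), 1e-6)
  # slow scanner drift (linear trend + a low-frequency cosine inside the
  # 128 s confound space) corrupts unfiltered estimates; the high-pass +
  # detrend path removes it exactly, leaving estimates invariant to it
  t_vol <- seq_len(nrow(Y))
  n_vol <- nrow(Y)
  drift <- outer(0.5 * t_vol + 25 * cos(pi * (t_vol - 0.5) / n_vol),
                 rnorm(ncol(Y)))
  est_raw <- lss_estimate(Y + drift, ev, run_length_s = rl, TR = 2)
  est_hp <- lss_estimate(Y + drift, ev, run_length_s = rl, TR = 2,
                         hp_cutoff_s = 128)
  est_hp_clean <- lss_estimate(Y, ev, run_length_s = rl, TR = 2,
                               hp_cutoff_s = 128)
  expect_equal(est_hp, est_hp_clean, tolerance = 1e-8)
  err_raw <- max(abs(est_raw - B)) / max(abs(B))
  err_hp <- max(abs(est_hp - B)) / max(abs(B))
  expect_lt(err_hp, err_raw)
  expect_lt(err_hp, 0.1)
  # all-zero BOLD gives all-zero betas
  est0 <- lss_estimate(Y * 0, ev, run_length_s = rl, TR = 2)
  expect_equal(max(abs(est0)), 0)
  # an additive offset is absorbed by the intercept
  est_off <- lss_estimate(Y + 7, ev, run_length_s = rl, TR = 2)
  expect_equal(est_off, est, tolerance = 1e-9)
  # permuting voxels permutes beta columns identically
  perm <- sample(ncol(Y))
  est_perm <- lss_estimate(Y[, perm], ev, run_length_s = rl, TR = 2)
  expect_equal(est_perm, est[, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("LS-S equals the single-GLM solution when trial regressors are orthogonal", {
  # events separated far beyond the HRF support: every trial regressor is
  # orthogonal to every other, so per-trial estimation and the joint
  # all-trials GLM agree
  # TR-aligned onsets so every trial's sampled regressor is an identical
  # translate (onsets incommensurate with the TR shift the sampled waveform
  # and reintroduce tiny cross-trial leakage)
  ev <- make_sparse_events(n_trials = 5, spacing = 46)
  rl <- 280
  set.seed(13)
  B <- matrix(rnorm(5 * 10), 5, 10)
  regs <- vapply(seq_len(5), function(r) {
    neurocompress:::convolve_events(ev$onset_s[r], ev$stim_duration_s[r],
                                    rl, 2)
  }, numeric(floor(rl / 2)))
  # noiseless: both estimators return the generating betas exactly
  Y0 <- simulate_bold(ev, B, run_length_s = rl, TR = 2, noise_sd = 0,
                      nuisance_amp = 0, seed = 2)
  lss0 <- lss_estimate(Y0, ev, run_length_s = rl, TR = 2)
  lsa0 <- qr.coef(qr(cbind(regs, 1)), Y0)[1:5, ]
  expect_equal(unname(lss0), unname(lsa0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # with noise the two designs differ only through the shared intercept
  # (HRF regressors are non-negative, hence never orthogonal to it), so the
  # solutions agree closely but not identically
  Y <- simulate_bold(ev, B, run_length_s = rl, TR = 2, noise_sd = 0.3,
                     nuisance_amp = 0, seed = 2)
  lss <- lss_estimate(Y, ev, run_length_s = rl, TR = 2)
  lsa <- qr.coef(qr(cbind(regs, 1)), Y)[1:5, ]
  expect_lt(max(abs(lss - lsa)) / max(abs(lsa)), 1e-2)
})

test_that("the linear forward model matches its building blocks", {
  ev <- make_sparse_events(n_trials = 1)
  Y <- simulate_bold(ev, matrix(2, 1, 1), run_length_s = 100, TR = 2,
                     noise_sd = 0, nuisance_amp = 0, seed = 1)
  reg <- neurocompress:::convolve_events(ev$onset_s, ev$stim_duration_s,
                                         100, 2)
  expect_equal(Y[, 1], 2 * reg)
  # zero betas, zero noise, zero nuisance -> flat series
  Y0 <- simulate_bold(ev, matrix(0, 1, 1), run_length_s = 100, TR = 2,
                      noise_sd = 0, nuisance_amp = 0, seed = 1)
  expect_equal(max(abs(Y0)), 0)
  expect_error(simulate_bold(ev, matrix(1, 1, 1), run_length_s = 100,
                             TR = -1), "TR must be positive")
  ev_bad <- ev
  ev_bad$onset_s <- 99
  expect_error(simulate_bold(ev_bad, matrix(1, 1, 1), run_length_s = 100,
                             TR = 2), "beyond the")
})
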