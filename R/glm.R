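#' Canonical double-gamma haemodynamic response kernel
#'
#' SPM-convention double gamma: a positive gamma density peaking near 5 s
#' minus a scaled undershoot gamma, sampled at `dt` and normalized to peak 1.
#' The kernel is causal (`h(0) = 0`).
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param duration_s Kernel length in seconds.
#' @param peak_delay,under_delay Shape parameters (seconds) of the response
#'   and undershoot gamma components.
#' @param peak_disp,under_disp Dispersions of the two components.
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @export
hrf_kernel <- function(dt = 0.1, duration_s = 32, peak_delay = 6,
                       under_delay = 16, peak_disp = 1, under_disp = 1,
                       ratio = 1 / 6) {
  if (dt <= 0) stop("dt must be positive")
  if (any(c(peak_delay, under_delay, peak_disp, under_disp) <= 0)) {
    stop("HRF shape parameters must be positive")
  }
  t <- seq(0, duration_s, by = dt)
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * dgamma(t, shape = under_delay / under_disp, scale = under_disp)
  h / max(h)
}

# Event regressor sampled at volume times: boxcar (or impulse for
# duration 0) on a fine dt grid, convolved with the HRF, then read out at
# t = 0, TR, 2 TR, ...
convolve_events <- function(onsets, durations, run_length_s, TR,
                            dt = 0.1, hrf = hrf_kernel(dt = dt)) {
  if (TR <= 0) stop("TR must be positive")
  n_fine <- ceiling(run_length_s / dt) + 1L
  stickf <- numeric(n_fine)
  for (e in seq_along(onsets)) {
    if (onsets[e] < 0 || onsets[e] + durations[e] > run_length_s) {
      stop("event at ", onsets[e], " s extends beyond the ", run_length_s,
           " s run")
    }
    i0 <- floor(onsets[e] / dt) + 1L
    i1 <- max(i0, ceiling((onsets[e] + durations[e]) / dt))
    stickf[i0:min(i1, n_fine)] <- stickf[i0:min(i1, n_fine)] + 1
  }
  conv <- convolve(stickf, rev(hrf), type = "open")[seq_len(n_fine)]
  n_vol <- floor(run_length_s / TR)
  vol_idx <- round(seq(0, by = TR, length.out = n_vol) / dt) + 1L
  conv[vol_idx]
}

# Events for one run in the column layout produced by make_trial_schedule();
# fills response-event onsets (impulse at time of response) if absent.
prepare_run_events <- function(events, default_rt = 1.25) {
  if (is.null(events$response_onset_s)) {
    events$response_onset_s <- events$onset_s + default_rt
  }
  events
}

#' Least-squares-separate design matrix for one target trial
#'
#' One regressor carries the target trial's 3.5 s boxcar convolved with the
#' HRF; a second carries all other stimulus events combined. Nuisance
#' regressors: correct-feedback and incorrect-feedback boxcars (2 s),
#' response-A and response-B impulses, six motion parameters, and an
#' intercept. Event regressors with no events (e.g. no incorrect feedback in
#' a run) are dropped and recorded in the `labels` attribute.
#'
#' @param events One run's trial table (columns `onset_s`, `stim_duration_s`,
#'   `feedback_onset_s`, `feedback_duration_s`, `correct`, `response`,
#'   `trial_index`).
#' @param run_length_s Run duration in seconds.
#' @param TR Repetition time in seconds.
#' @param target_trial Value of `trial_index` identifying the trial of
#'   interest.
#' @param motion Optional volumes x 6 motion-parameter matrix (zeros if
#'   omitted).
#' @param dt Microtime resolution for convolution.
#' @param hrf HRF kernel sampled at `dt`.
#' @return Numeric matrix (volumes x regressors) with column names; the
#'   target regressor is column `"target"`.
#' @export
build_design <- function(events, run_length_s, TR = 2, target_trial,
                         motion = NULL, dt = 0.1,
                         hrf = hrf_kernel(dt = dt)) {
  events <- prepare_run_events(events)
  if (!target_trial %in% events$trial_index) {
    stop("target_trial ", target_trial, " not present in events")
  }
  is_target <- events$trial_index == target_trial
  conv <- function(sel, onset, duration) {
    if (!any(sel)) return(NULL)
    convolve_events(onset[sel], duration[sel], run_length_s, TR, dt, hrf)
  }
  cols <- list(
    target = conv(is_target, events$onset_s, events$stim_duration_s),
    others = conv(!is_target, events$onset_s, events$stim_duration_s),
    feedback_correct = conv(events$correct %in% TRUE,
                            events$feedback_onset_s,
                            events$feedback_duration_s),
    feedback_incorrect = conv(events$correct %in% FALSE,
                              events$feedback_onset_s,
                              events$feedback_duration_s),
    response_A = conv(events$response %in% "A", events$response_onset_s,
                      rep(0, nrow(events))),
    response_B = conv(events$response %in% "B", events$response_onset_s,
                      rep(0, nrow(events)))
  )
  cols <- cols[!vapply(cols, is.null, logical(1L))]
  X <- do.call(cbind, cols)
  n_vol <- nrow(X)
  if (is.null(motion)) motion <- matrix(0, n_vol, 6L)
  if (nrow(motion) != n_vol || ncol(motion) != 6L) {
    stop("motion must be a ", n_vol, " x 6 matrix")
  }
  colnames(motion) <- paste0("motion", 1:6)
  # all-zero motion columns (synthetic data without head motion) carry no
  # information and would make every design rank-deficient
  motion <- motion[, apply(motion != 0, 2L, any), drop = FALSE]
  X <- cbind(X, motion, intercept = 1)
  attr(X, "labels") <- colnames(X)
  X
}

# Project out a high-pass/detrend confound basis (intercept, linear trend,
# and discrete-cosine components with period > cutoff) from a matrix.
highpass_projector <- function(n_vol, TR, cutoff_s = 128) {
  t <- seq_len(n_vol)
  C <- cbind(1, t - mean(t))
  if (!is.null(cutoff_s) && cutoff_s > 0) {
    K <- floor(2 * n_vol * TR / cutoff_s)
    for (k in seq_len(K)) {
      C <- cbind(C, cos(pi * k * (t - 0.5) / n_vol))
    }
  }
  diag(n_vol) - C %*% solve(crossprod(C), t(C))
}

#' Least-squares-separate single-trial beta estimation
#'
#' For each stimulus trial in a run, fits an ordinary-least-squares GLM whose
#' design isolates that trial (one target regressor, one combined
#' other-trials regressor, feedback/response/motion nuisances) and collects
#' the target beta across voxels into a trial x voxel beta series. When
#' `hp_cutoff_s` is set, a high-pass + linear-detrend confound basis is
#' projected out of both the data and the regressors (the intercept is then
#' part of the confound set), leaving the trial estimates unbiased.
#'
#' @param bold Volumes x voxels BOLD matrix.
#' @param events One run's trial table (see [build_design()]).
#' @param run_length_s Run duration in seconds.
#' @param TR Repetition time.
#' @param motion Optional volumes x 6 motion matrix.
#' @param hp_cutoff_s High-pass cutoff in seconds (`NULL` to disable
#'   filtering).
#' @param dt,hrf Convolution resolution and kernel.
#' @return Trials x voxels matrix of target-regressor estimates, rows in
#'   `events$trial_index` order, with attribute `trial_index`.
#' @export
lss_estimate <- function(bold, events, run_length_s, TR = 2, motion = NULL,
                         hp_cutoff_s = NULL, dt = 0.1,
                         hrf = hrf_kernel(dt = dt)) {
  events <- prepare_run_events(events)
  n_vol <- nrow(bold)
  P <- NULL
  if (!is.null(hp_cutoff_s)) {
    P <- highpass_projector(n_vol, TR, hp_cutoff_s)
    bold <- P %*% bold
  }
  betas <- matrix(NA_real_, nrow(events), ncol(bold))
  for (r in seq_len(nrow(events))) {
    X <- build_design(events, run_length_s, TR, events$trial_index[r],
                      motion = motion, dt = dt, hrf = hrf)
    if (nrow(X) != n_vol) {
      stop("bold has ", n_vol, " volumes but the design implies ", nrow(X))
    }
    if (!is.null(P)) {
      X <- P %*% X[, colnames(X) != "intercept", drop = FALSE]
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("rank-deficient design for trial ", events$trial_index[r],
              "; using pseudo-inverse")
      sv <- svd(X)
      keep <- sv$d > max(sv$d) * 1e-10
      coef <- sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% bold) / sv$d[keep])
    } else {
      coef <- qr.coef(qx, bold)
    }
    betas[r, ] <- coef[1L, ]
  }
  attr(betas, "trial_index") <- events$trial_index
  betas
}
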