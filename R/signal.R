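#' Signal specification for synthetic activation patterns
#'
#' Defines the generative conditions for trial-wise activation patterns: the
#' planted intrinsic dimensionality and category separation per (problem,
#' learning block), the per-voxel signal amplitude, and the noise level.
#'
#' Defaults emulate the study's predicted structure: intrinsic rank falls
#' across blocks fastest for the low-complexity problem (8,6,4,2), slower for
#' medium (8,7,6,5) and not at all for high (8,8,8,8), so compression rises
#' with learning most for simple goals; category separation rises over blocks
#' and falls with complexity (low 0.8..2.6, medium 0.6..1.8, high 0.4..1.0,
#' in units of noise SD along the category axis), so PC-loading category
#' discrimination shows the matching directions.
#'
#' @param intrinsic_rank 3 x 4 matrix (rows low/medium/high, columns blocks
#'   1-4) of planted ranks, each in `[1, 32]`.
#' @param category_separation 3 x 4 matrix of class-mean separations.
#' @param amplitude Per-voxel signal SD in units of `noise_sd`.
#' @param noise_sd I.i.d. Gaussian noise SD (>= 0).
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(intrinsic_rank = rbind(low = c(8, 6, 4, 2),
                                               medium = c(8, 7, 6, 5),
                                               high = c(8, 8, 8, 8)),
                        category_separation = rbind(low = seq(0.8, 2.6, by = 0.6),
                                                    medium = seq(0.6, 1.8, by = 0.4),
                                                    high = seq(0.4, 1.0, by = 0.2)),
                        amplitude = 3.5, noise_sd = 1) {
  stopifnot(is.matrix(intrinsic_rank), dim(intrinsic_rank) == c(3L, 4L),
            is.matrix(category_separation),
            dim(category_separation) == c(3L, 4L))
  if (any(intrinsic_rank < 1 | intrinsic_rank > 32)) {
    stop("intrinsic_rank must lie in [1, 32]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  rownames(intrinsic_rank) <- rownames(category_separation) <- problem_levels()
  structure(
    list(intrinsic_rank = intrinsic_rank,
         category_separation = category_separation,
         amplitude = amplitude, noise_sd = noise_sd),
    class = "signal_spec"
  )
}

#' Ellipsoidal brain-like mask in a box volume
#'
#' @param dim Length-3 integer volume dimensions (default `c(20, 20, 20)`).
#' @param semiaxes Ellipsoid semi-axes in voxels (default `dim/2 - 1`).
#' @return Logical 3-D array.
#' @export
ellipsoid_mask <- function(dim = c(20L, 20L, 20L), semiaxes = dim / 2 - 1) {
  ctr <- (dim + 1) / 2
  g <- expand.grid(x = seq_len(dim[1L]), y = seq_len(dim[2L]),
                   z = seq_len(dim[3L]))
  d2 <- ((g$x - ctr[1L]) / semiaxes[1L])^2 +
    ((g$y - ctr[2L]) / semiaxes[2L])^2 +
    ((g$z - ctr[3L]) / semiaxes[3L])^2
  array(d2 <= 1, dim = dim)
}

#' Trial x voxel beta-series container
#'
#' @param betas Trials x in-mask-voxels matrix.
#' @param mask Logical 3-D array; `sum(mask)` must equal `ncol(betas)`.
#' @param meta Named list of metadata (participant, problem, run, ...).
#' @return A `beta_series` object.
#' @export
beta_series <- function(betas, mask, meta = list()) {
  if (sum(mask) != ncol(betas)) {
    stop("mask voxel count (", sum(mask), ") != beta columns (",
         ncol(betas), ")")
  }
  structure(list(betas = betas, mask = mask, meta = meta),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("beta_series:", nrow(x$betas), "trials x", ncol(x$betas),
      "in-mask voxels; volume", paste(dim(x$mask), collapse = "x"), "\n")
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=",
                    collapse = ", "), "\n")
  }
  invisible(x)
}

# Low-rank structured signal + noise for one run of 32 trials.
# Column 1 of the trial-score matrix carries the class axis (the problem's
# relevant-attribute combination): class A trials at +sep/2, B at -sep/2 on
# top of a full-variance component, so the planted rank is exactly `rank`
# and class separation scales with `sep`.
simulate_run_betas <- function(true_class, rank, sep, amplitude, noise_sd,
                               n_voxels) {
  n <- length(true_class)
  if (rank > n) stop("intrinsic rank (", rank, ") exceeds trial count ", n)
  # orthonormal zero-mean score directions, unit sample variance
  raw <- matrix(rnorm(n * rank), n, rank)
  raw <- sweep(raw, 2L, colMeans(raw))
  Q <- qr.Q(qr(raw))
  # class contrast, centered and orthogonalized against the score
  # directions so the planted components keep exactly equal variance plus a
  # clean category increment on component 1
  z <- ifelse(true_class == "A", 0.5, -0.5) * sep
  z <- z - mean(z)
  z <- z - Q %*% crossprod(Q, z)
  scores <- Q * sqrt(n - 1)
  scores[, 1L] <- scores[, 1L] + z
  # orthonormal voxel axes scaled to per-voxel signal SD = amplitude
  W <- matrix(rnorm(rank * n_voxels), rank, n_voxels)
  W <- t(qr.Q(qr(t(W)))) * amplitude * sqrt(n_voxels / rank)
  signal <- scores %*% W
  if (noise_sd > 0) {
    signal <- signal + matrix(rnorm(n * n_voxels, sd = noise_sd), n, n_voxels)
  }
  signal
}

#' Simulate trial-wise activation patterns for a participant
#'
#' For every (problem, run) in the trial table, generates a 32 x voxels
#' activation matrix as a low-rank structured signal — planted rank and
#' class-mean separation taken from the `signal_spec` for that problem and
#' block — plus i.i.d. Gaussian noise. The class axis is aligned with the
#' problem's relevant attributes through the trials' true categories, so
#' compression and category discrimination co-vary with problem complexity
#' by construction.
#'
#' @param trials Trial table for one participant (responses optional).
#' @param spec A [signal_spec()].
#' @param mask Logical 3-D array defining the voxel set.
#' @param seed Integer seed; generation is reproducible.
#' @return Named list of [beta_series()] objects, one per `problem_run`.
#' @export
simulate_beta_series <- function(trials, spec, mask = ellipsoid_mask(),
                                 seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"))
  n_vox <- sum(mask)
  with_seed(seed, {
    out <- list()
    for (problem in problem_levels()) {
      for (run in 1:4) {
        sel <- trials$problem == problem & trials$run == run
        if (!any(sel)) next
        tr <- trials[sel, , drop = FALSE]
        tr <- tr[order(tr$trial_index), , drop = FALSE]
        mat <- simulate_run_betas(
          true_class = tr$true_class,
          rank = spec$intrinsic_rank[problem, run],
          sep = spec$category_separation[problem, run],
          amplitude = spec$amplitude, noise_sd = spec$noise_sd,
          n_voxels = n_vox
        )
        out[[paste(problem, run, sep = "_run")]] <- beta_series(
          mat, mask,
          meta = list(participant_id = tr$participant_id[1L],
                      problem = problem, run = run)
        )
      }
    }
    out
  })
}

#' Forward-simulate BOLD time series from trial betas
#'
#' Linear forward model: each trial's activation pattern enters the time
#' series through its 3.5 s boxcar convolved with the HRF; feedback (2 s
#' boxcar, split by correctness) and response (impulse) events contribute
#' fixed random spatial patterns; i.i.d. Gaussian noise is added. The event
#' convention matches [build_design()], so least-squares-separate estimation
#' on the simulated series recovers the generating betas when events are
#' well separated and noise is zero.
#'
#' @param events One run's trial table.
#' @param betas Trials x voxels matrix of generating patterns.
#' @param run_length_s Run duration in seconds.
#' @param TR Repetition time (default 2 s).
#' @param noise_sd Gaussian noise SD.
#' @param nuisance_amp Amplitude of the feedback/response patterns.
#' @param seed Integer seed.
#' @param dt,hrf Convolution resolution and kernel.
#' @return Volumes x voxels BOLD matrix.
#' @export
simulate_bold <- function(events, betas, run_length_s, TR = 2, noise_sd = 0,
                          nuisance_amp = 0.5, seed = 1L, dt = 0.1,
                          hrf = hrf_kernel(dt = dt)) {
  if (TR <= 0) stop("TR must be positive")
  events <- prepare_run_events(events)
  stopifnot(nrow(events) == nrow(betas))
  n_vox <- ncol(betas)
  with_seed(seed, {
    n_vol <- floor(run_length_s / TR)
    Y <- matrix(0, n_vol, n_vox)
    for (r in seq_len(nrow(events))) {
      reg <- convolve_events(events$onset_s[r], events$stim_duration_s[r],
                             run_length_s, TR, dt, hrf)
      Y <- Y + tcrossprod(reg, betas[r, ])
    }
    nuis <- list(
      list(sel = events$correct %in% TRUE, onset = events$feedback_onset_s,
           dur = events$feedback_duration_s),
      list(sel = events$correct %in% FALSE, onset = events$feedback_onset_s,
           dur = events$feedback_duration_s),
      list(sel = events$response %in% "A", onset = events$response_onset_s,
           dur = rep(0, nrow(events))),
      list(sel = events$response %in% "B", onset = events$response_onset_s,
           dur = rep(0, nrow(events)))
    )
    for (nu in nuis) {
      if (!any(nu$sel)) next
      reg <- convolve_events(nu$onset[nu$sel], nu$dur[nu$sel], run_length_s,
                             TR, dt, hrf)
      pattern <- rnorm(n_vox, sd = nuisance_amp)
      Y <- Y + tcrossprod(reg, pattern)
    }
    if (noise_sd > 0) {
      Y <- Y + matrix(rnorm(n_vol * n_vox, sd = noise_sd), n_vol, n_vox)
    }
    Y
  })
}
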