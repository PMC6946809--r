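# Shared fixtures built in code.

# One participant's schedule with responses from a SUSTAIN learner.
make_learner_trials <- function(seed = 1L, params = sustain_params(),
                                problem_order = c("high", "low", "medium")) {
  bank <- make_problem_bank(seed = seed, randomize_feature_mapping = TRUE)
  sched <- make_trial_schedule(bank, problem_order = problem_order,
                               seed = seed)
  simulate_learner(sched, params, seed = seed + 1000L)
}

# Well-separated passive-viewing events for LS-S round trips: no feedback or
# response events, spacing longer than boxcar + HRF support.
make_sparse_events <- function(n_trials = 6L, spacing = 40) {
  data.frame(
    onset_s = seq(10, by = spacing, length.out = n_trials),
    stim_duration_s = 3.5,
    feedback_onset_s = NA_real_, feedback_duration_s = 2,
    correct = NA, response = NA_character_,
    trial_index = seq_len(n_trials)
  )
}

# Balanced A/B labels for 32 trials.
balanced_labels <- function(n = 32L) rep(c("A", "B"), n / 2L)

# Independent PCA-count oracle: eigenvalues of the voxel covariance via
# eigen() on the cross-product (a different route than pca_k's SVD of the
# centered data matrix).
oracle_pca_k <- function(patterns, var_threshold = 0.9) {
  centered <- sweep(patterns, 2L, colMeans(patterns))
  ev <- eigen(tcrossprod(centered), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  which(cumsum(ev) / sum(ev) >= var_threshold - 1e-12)[1L]
}

# Brute-force discrimination score straight from raw patterns.
oracle_discrimination <- function(patterns, labels, var_threshold = 0.9) {
  centered <- sweep(patterns, 2L, colMeans(patterns))
  sv <- svd(centered)
  evr <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(evr) >= var_threshold - 1e-12)[1L]
  proj <- centered %*% sv$v[, seq_len(k), drop = FALSE]
  dif <- abs(colMeans(proj[labels == "A", , drop = FALSE]) -
               colMeans(proj[labels == "B", , drop = FALSE]))
  sum(evr[seq_len(k)] * dif)
}

# Naive per-center searchlight loop over pca_k (the R-level oracle for the
# C++ kernel).
naive_searchlight <- function(bs, radius, var_threshold = 0.9,
                              min_sphere_voxels = 10L) {
  dims <- dim(bs$mask)
  vox <- which(bs$mask)
  xyz <- arrayInd(vox, dims)
  offs <- sphere_offsets(radius)
  comp <- k <- array(NA_real_, dim = dims)
  for (ci in seq_along(vox)) {
    nb <- sweep(offs, 2L, xyz[ci, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1L] + dims[1L] * ((nb[, 2L] - 1L) + dims[2L] * (nb[, 3L] - 1L))
    lin <- lin[bs$mask[lin]]
    cols <- match(lin, vox)
    if (length(cols) < min_sphere_voxels) next
    res <- pca_k(bs$betas[, cols, drop = FALSE], var_threshold)
    comp[vox[ci]] <- res$compression
    k[vox[ci]] <- res$k
  }
  list(compression = comp, k = k)
}
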