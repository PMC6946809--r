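#' Block-by-complexity linear mixed-effects regression
#'
#' The group model applied to compression-type outcomes: fixed effects of
#' learning block, problem complexity (coded 1/2/3), their interaction, and
#' optional covariates (typically accuracy), with a participant random
#' intercept. Estimated by REML with Satterthwaite degrees of freedom.
#'
#' @param data Long-format data frame with columns `participant_id`, `block`,
#'   `complexity` (numeric), the covariates, and the outcome.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of additional fixed-effect columns.
#' @param center Center `block` and `complexity` before fitting, so main
#'   effects are evaluated at the design mean in the presence of the
#'   interaction.
#' @return List with `model` (a `lmerModLmerTest`), and `coefficients` (data
#'   frame of estimates, standard errors, Satterthwaite df, t and p values).
#' @export
block_complexity_lme <- function(data, outcome = "compression",
                                 covariates = "accuracy", center = FALSE) {
  needed <- c("participant_id", "block", "complexity", covariates, outcome)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (center) {
    data$block <- data$block - mean(data$block)
    data$complexity <- data$complexity - mean(data$complexity)
  }
  rhs <- paste(c("block * complexity", covariates, "(1 | participant_id)"),
               collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  coefs <- as.data.frame(summary(fit)$coefficients)
  names(coefs) <- c("estimate", "se", "df", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  list(model = fit, coefficients = coefs[, c("term", "estimate", "se", "df",
                                             "t", "p")],
       singular = lme4::isSingular(fit))
}

#' Voxel-wise mixed-effects interaction map
#'
#' Fits the block-by-complexity mixed model at every voxel of a stack of
#' compression maps and stores the interaction t-statistic (and p-value).
#' Voxels where the fit fails or is singular are flagged and left `NA`.
#'
#' @param values Observations x voxels matrix (one row per participant x
#'   problem x block map, columns aligned across maps).
#' @param panel Data frame describing the rows of `values`: columns
#'   `participant_id`, `block`, `complexity`, plus covariates.
#' @param mask Optional logical 3-D array with `sum(mask) == ncol(values)`;
#'   when given, maps are returned as 3-D arrays.
#' @param covariates Additional fixed-effect columns in `panel`.
#' @return A `stat_map` list: `t`, `p` (vectors or 3-D arrays), the
#'   interaction `estimate`, `df`, `n_failed`, and the mask.
#' @export
voxelwise_interaction_map <- function(values, panel, mask = NULL,
                                      covariates = "accuracy") {
  stopifnot(nrow(values) == nrow(panel))
  if (!is.null(mask) && sum(mask) != ncol(values)) {
    stop("mask voxel count must equal ncol(values)")
  }
  n_vox <- ncol(values)
  t_v <- p_v <- est_v <- df_v <- rep(NA_real_, n_vox)
  n_failed <- 0L
  for (v in seq_len(n_vox)) {
    panel$.y <- values[, v]
    fit <- tryCatch(
      block_complexity_lme(panel, outcome = ".y", covariates = covariates),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$singular) {
      n_failed <- n_failed + 1L
      next
    }
    row <- fit$coefficients[fit$coefficients$term == "block:complexity", ]
    t_v[v] <- row$t
    p_v[v] <- row$p
    est_v[v] <- row$estimate
    df_v[v] <- row$df
  }
  shape <- function(x) {
    if (is.null(mask)) return(x)
    vol <- array(NA_real_, dim = dim(mask))
    vol[which(mask)] <- x
    vol
  }
  structure(
    list(t = shape(t_v), p = shape(p_v), estimate = shape(est_v),
         df = shape(df_v), n_failed = n_failed, mask = mask),
    class = "stat_map"
  )
}

# 18-connectivity (faces + edges) neighbor offsets, the second-nearest
# neighbor convention.
connectivity_offsets <- function(connectivity = 18L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(g^2)
  keep <- switch(as.character(connectivity),
                 "6" = d2 == 1, "18" = d2 >= 1 & d2 <= 2, "26" = d2 >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds `|t|` two-sided at `t_threshold` (or at the two-sided critical
#' value for `voxel_p` with `df` degrees of freedom), labels connected
#' components by breadth-first flood fill under the given connectivity, and
#' keeps clusters of at least `extent` voxels.
#'
#' @param t_map 3-D array of t-statistics (`NA` outside the mask).
#' @param t_threshold Two-sided |t| threshold; overrides `voxel_p`.
#' @param voxel_p Two-sided voxel-wise p threshold (default 0.001).
#' @param df Degrees of freedom used to convert `voxel_p` into a t value.
#' @param extent Minimum cluster size in voxels.
#' @param connectivity 6 (faces), 18 (faces+edges, default) or 26.
#' @return Data frame with one row per cluster: `cluster`, `size`,
#'   `peak_x/y/z` (1-based voxel indices), `peak_t`.
#' @export
cluster_extract <- function(t_map, t_threshold = NULL, voxel_p = 0.001,
                            df = Inf, extent = 1L, connectivity = 18L) {
  if (is.null(t_threshold)) {
    t_threshold <- stats::qt(1 - voxel_p / 2, df = df)
  }
  if (extent <= 0) stop("extent must be positive")
  dims <- dim(t_map)
  supra <- !is.na(t_map) & abs(t_map) >= t_threshold
  idx_supra <- which(supra)
  if (length(idx_supra) == 0L) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_t = numeric(0)))
  }
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dim = dims)
  next_label <- 0L
  out <- list()
  for (start in idx_supra) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      xyz <- arrayInd(cur, dims)
      nb <- sweep(offs, 2L, as.integer(xyz), "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1L] + dims[1L] * ((nb[, 2L] - 1L) + dims[2L] * (nb[, 3L] - 1L))
      lin <- lin[supra[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- next_label
        queue <- c(queue, lin)
      }
    }
    peak <- members[which.max(abs(t_map[members]))]
    pk <- arrayInd(peak, dims)
    out[[next_label]] <- data.frame(
      cluster = next_label, size = length(members),
      peak_x = pk[1L], peak_y = pk[2L], peak_z = pk[3L],
      peak_t = t_map[peak]
    )
  }
  res <- do.call(rbind, out)
  res <- res[res$size >= extent, , drop = FALSE]
  res <- res[order(-res$size), , drop = FALSE]
  res$cluster <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Trial-by-trial behavioral learning regression
#'
#' Mixed-effects logistic regression of accuracy on stimulus repetition,
#' problem complexity and learning order, with participant random
#' intercepts; each fixed effect is assessed by a likelihood-ratio
#' chi-square (single-term deletion).
#'
#' @param trials Trial table with filled responses across participants.
#' @return List with the fitted `model` and `tests` (data frame of LRT
#'   chi-squares, df and p per fixed effect).
#' @export
behavioral_learning_regression <- function(trials) {
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  trials$repetition <- stimulus_repetition(trials)
  trials$complexity <- problem_complexity(trials$problem)
  trials$order <- trials$problem_order_idx
  fit <- lme4::glmer(
    correct ~ repetition + complexity + order + (1 | participant_id),
    data = trials, family = stats::binomial,
    control = lme4::glmerControl(calc.derivs = FALSE)
  )
  lrt <- suppressMessages(drop1(fit, test = "Chisq"))
  tests <- data.frame(
    term = rownames(lrt)[-1L],
    chisq = lrt$LRT[-1L],
    df = lrt$npar[-1L],
    p = lrt[["Pr(Chi)"]][-1L]
  )
  list(model = fit, tests = tests)
}

# Cumulative presentation count of each stimulus within participant and
# problem, in experienced order.
stimulus_repetition <- function(trials) {
  ord <- order(trials$participant_id, trials$problem_order_idx, trials$run,
               trials$trial_index)
  rep_count <- integer(nrow(trials))
  key <- paste(trials$participant_id, trials$problem, trials$stimulus_code)
  rep_count[ord] <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
  rep_count
}

#' Per-participant learning curves
#'
#' Mean accuracy over consecutive blocks of `block_size` trials (default 16)
#' within each (participant, problem), in experienced order.
#'
#' @param trials Trial table with filled `correct`.
#' @param block_size Trials per behavioral block; must divide the per-problem
#'   trial count.
#' @return Data frame with `participant_id`, `problem`, `behav_block`,
#'   `accuracy`.
#' @export
learning_curves <- function(trials, block_size = 16L) {
  trials <- trials[order(trials$participant_id, trials$problem_order_idx,
                         trials$run, trials$trial_index), , drop = FALSE]
  out <- list()
  for (key in unique(paste(trials$participant_id, trials$problem, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1L]]
    sel <- trials$participant_id == parts[1L] & trials$problem == parts[2L]
    acc <- trials$correct[sel]
    if (length(acc) %% block_size != 0L) {
      stop("block_size must divide the per-problem trial count")
    }
    blocks <- rep(seq_len(length(acc) / block_size), each = block_size)
    out[[key]] <- data.frame(
      participant_id = parts[1L], problem = parts[2L],
      behav_block = seq_len(max(blocks)),
      accuracy = as.numeric(tapply(acc, blocks, mean)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regression relating neural compression to attention compression
#'
#' Mixed model predicting attention compression from neural compression,
#' learning block, problem complexity, learning order and accuracy, with a
#' participant random intercept. Reports the neural-compression coefficient
#' with a Wald 95% interval and Satterthwaite p-value, plus partial
#' residuals of both measures (each residualized on the remaining
#' predictors) for plotting.
#'
#' @param neural Data frame with `participant_id`, `problem`, `block`,
#'   `neural_compression`, `order`, `accuracy`.
#' @param attention Data frame with `participant_id`, `problem`, `block`,
#'   `attention_compression`.
#' @return List with `coefficient`, `ci` (length 2), `p`, the fitted
#'   `model`, and `partial_residuals` (data frame).
#' @export
compression_attention_regression <- function(neural, attention) {
  merged <- merge(neural, attention,
                  by = c("participant_id", "problem", "block"))
  if (nrow(merged) == 0L) {
    stop("neural and attention tables share no (participant, problem, block) rows")
  }
  if (nrow(merged) < nrow(attention)) {
    warning("join dropped ", nrow(attention) - nrow(merged), " attention rows")
  }
  merged$complexity <- problem_complexity(merged$problem)
  fit <- lmerTest::lmer(
    attention_compression ~ neural_compression + block + complexity +
      order + accuracy + (1 | participant_id),
    data = merged, REML = TRUE
  )
  co <- summary(fit)$coefficients
  est <- co["neural_compression", "Estimate"]
  se <- co["neural_compression", "Std. Error"]
  # partial residuals: each measure residualized on the other predictors
  covs <- ~ block + complexity + order + accuracy
  res_y <- stats::resid(stats::lm(stats::update(covs, attention_compression ~ .),
                                  data = merged))
  res_x <- stats::resid(stats::lm(stats::update(covs, neural_compression ~ .),
                                  data = merged))
  list(
    coefficient = est,
    ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
    p = co["neural_compression", "Pr(>|t|)"],
    model = fit,
    partial_residuals = data.frame(
      participant_id = merged$participant_id, problem = merged$problem,
      block = merged$block, neural = res_x, attention = res_y
    )
  )
}
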