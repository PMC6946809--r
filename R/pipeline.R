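#' Pipeline configuration
#'
#' Collects every knob for an end-to-end run: cohort size, generative
#' conditions, SUSTAIN settings, searchlight geometry, and the statistics
#' stage's problem subset (e.g. low+medium only, mirroring the
#' counterbalanced-order control analysis).
#'
#' @param out_dir Output directory.
#' @param n_participants Number of simulated participants (default 23).
#' @param seed Master seed; all per-participant seeds derive from it.
#' @param volume_dim Length-3 volume dimensions for the synthetic mask.
#' @param spec A [signal_spec()].
#' @param generating_params [sustain_params()] driving the simulated
#'   learners.
#' @param fit_sustain Fit SUSTAIN to each simulated participant (`TRUE`) or
#'   extract attention trajectories at the generating parameters (`FALSE`).
#' @param de_control List passed to [de_optimize()] when fitting.
#' @param radius,var_threshold,min_sphere_voxels Searchlight settings.
#' @param problem_subset Problems entering the stats stage (default all
#'   three).
#' @param write_nifti Write beta series and compression maps as NIfTI files
#'   (slower; the TSV summaries are always written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, n_participants = 23L, seed = 1L,
                            volume_dim = c(20L, 20L, 20L),
                            spec = signal_spec(),
                            generating_params = sustain_params(),
                            fit_sustain = FALSE,
                            de_control = list(max_gen = 60L),
                            radius = 4, var_threshold = 0.9,
                            min_sphere_voxels = 10L,
                            problem_subset = problem_levels(),
                            write_nifti = FALSE) {
  stopifnot(n_participants >= 1L, length(volume_dim) == 3L,
            all(problem_subset %in% problem_levels()))
  structure(
    list(out_dir = out_dir, n_participants = as.integer(n_participants),
         seed = as.integer(seed), volume_dim = as.integer(volume_dim),
         spec = spec, generating_params = generating_params,
         fit_sustain = fit_sustain, de_control = de_control,
         radius = radius, var_threshold = var_threshold,
         min_sphere_voxels = as.integer(min_sphere_voxels),
         problem_subset = problem_subset, write_nifti = write_nifti),
    class = "pipeline_config"
  )
}

# Deterministic per-participant sub-seed, kept below 2^31.
derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 7919 + i * 104729 + salt * 15485863) %%
               2147483647)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: simulate (schedules, SUSTAIN learners, beta series), fit
#' (attention trajectories, optionally by maximum-likelihood fitting),
#' compress (searchlight maps and their in-mask means), discriminate
#' (whole-mask PCA discrimination scores), stats (block-by-complexity mixed
#' models on compression and discrimination, and the neural-to-attention
#' regression). Every stage writes TSV outputs under `out_dir` and a
#' manifest records seeds and settings; identical configs give bitwise-equal
#' TSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the key tables: `trials`,
#'   `learning_curves`, `attention`, `compression`, `discrimination`, and
#'   `stats` (coefficient tables), plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  for (d in c("", "data", "fits", "maps", "stats", "logs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_file <- file.path(out, "logs", "pipeline.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(name, paste("FAILED:", conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mask <- ellipsoid_mask(config$volume_dim)
  pids <- sprintf("sub-%02d", seq_len(config$n_participants))

  # --- simulate -------------------------------------------------------------
  trials_all <- list()
  betas_all <- list()
  stage("simulate", {
    for (i in seq_along(pids)) {
      s <- derive_seed(config$seed, i)
      bank <- make_problem_bank(seed = s, randomize_feature_mapping = TRUE)
      lowmed <- if (i %% 2L == 0L) c("low", "medium") else c("medium", "low")
      sched <- make_trial_schedule(bank, problem_order = c("high", lowmed),
                                   seed = s, participant_id = pids[i])
      tr <- simulate_learner(sched, config$generating_params,
                             seed = derive_seed(config$seed, i, 1L))
      trials_all[[i]] <- tr
      betas_all[[pids[i]]] <- simulate_beta_series(
        tr, config$spec, mask, seed = derive_seed(config$seed, i, 2L)
      )
    }
    log_line("simulate", paste(length(pids), "participants simulated"))
  })
  trials <- do.call(rbind, trials_all)
  utils::write.table(trials, file.path(out, "data", "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (config$write_nifti) {
    stage("simulate", write_dataset(file.path(out, "data"), trials,
                                    betas_all, mask))
  }
  curves <- learning_curves(trials)
  utils::write.table(curves, file.path(out, "data", "learning_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- fit ------------------------------------------------------------------
  attention <- stage("fit-sustain", {
    rows <- list()
    for (i in seq_along(pids)) {
      tr <- trials_all[[i]]
      if (config$fit_sustain) {
        fit <- fit_sustain(tr, seed = derive_seed(config$seed, i, 3L),
                           control = config$de_control)
        traj <- fit$attention
        jsonlite::write_json(
          list(participant_id = pids[i],
               params = unclass(fit$params), nll = fit$nll,
               optimizer = fit$optimizer),
          file.path(out, "fits", paste0(pids[i], "_sustain.json")),
          auto_unbox = TRUE, digits = NA
        )
      } else {
        traj <- attention_trajectory(config$generating_params, tr)
      }
      rows[[i]] <- blockwise_attention_compression(traj)
    }
    do.call(rbind, rows)
  })
  utils::write.table(attention,
                     file.path(out, "fits", "attention_compression.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_line("fit-sustain",
           if (config$fit_sustain) "maximum-likelihood fits" else
             "trajectories at generating parameters")

  # --- compress + discriminate ---------------------------------------------
  acc_block <- aggregate(
    correct ~ participant_id + problem + run, data = trials, FUN = mean
  )
  comp_rows <- list()
  disc_rows <- list()
  stage("compress", {
    for (pid in pids) {
      for (key in names(betas_all[[pid]])) {
        bs <- betas_all[[pid]][[key]]
        cmap <- searchlight_compression(
          bs, radius = config$radius, var_threshold = config$var_threshold,
          min_sphere_voxels = config$min_sphere_voxels
        )
        if (config$write_nifti) {
          write_map_nifti(cmap$compression, file.path(
            out, "maps",
            sprintf("%s_problem-%s_block-%d_compression.nii.gz",
                    pid, bs$meta$problem, bs$meta$run)
          ))
        }
        roi <- pca_k(bs$betas, var_threshold = config$var_threshold)
        labels <- trials$true_class[
          trials$participant_id == pid & trials$problem == bs$meta$problem &
            trials$run == bs$meta$run
        ][order(trials$trial_index[
          trials$participant_id == pid & trials$problem == bs$meta$problem &
            trials$run == bs$meta$run
        ])]
        disc <- pc_category_discrimination(roi, labels)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          participant_id = pid, problem = bs$meta$problem,
          block = bs$meta$run,
          compression = mean(cmap$compression, na.rm = TRUE),
          roi_compression = roi$compression,
          mean_activation = mean(bs$betas)
        )
        disc_rows[[length(disc_rows) + 1L]] <- data.frame(
          participant_id = pid, problem = bs$meta$problem,
          block = bs$meta$run, score = disc$score, k = disc$k
        )
      }
    }
  })
  compression <- do.call(rbind, comp_rows)
  discrimination <- do.call(rbind, disc_rows)
  add_covariates <- function(df) {
    df$complexity <- problem_complexity(df$problem)
    ord <- unique(trials[, c("participant_id", "problem",
                             "problem_order_idx")])
    df <- merge(df, ord, by = c("participant_id", "problem"))
    names(df)[names(df) == "problem_order_idx"] <- "order"
    df <- merge(df, acc_block,
                by.x = c("participant_id", "problem", "block"),
                by.y = c("participant_id", "problem", "run"))
    names(df)[names(df) == "correct"] <- "accuracy"
    df[order(df$participant_id, df$problem, df$block), , drop = FALSE]
  }
  compression <- add_covariates(compression)
  discrimination <- add_covariates(discrimination)
  utils::write.table(compression, file.path(out, "maps", "compression.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(discrimination,
                     file.path(out, "stats", "discrimination.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_line("compress", paste(nrow(compression), "maps summarized"))

  # --- stats ----------------------------------------------------------------
  stats_out <- stage("stats", {
    comp_sub <- compression[compression$problem %in% config$problem_subset, ]
    disc_sub <- discrimination[
      discrimination$problem %in% config$problem_subset, ]
    comp_lme <- block_complexity_lme(comp_sub, outcome = "compression")
    disc_lme <- block_complexity_lme(disc_sub, outcome = "score",
                                     center = TRUE)
    neural <- data.frame(
      participant_id = comp_sub$participant_id, problem = comp_sub$problem,
      block = comp_sub$block, neural_compression = comp_sub$compression,
      order = comp_sub$order, accuracy = comp_sub$accuracy
    )
    att_sub <- attention[attention$problem %in% config$problem_subset, ]
    att_reg <- compression_attention_regression(neural, att_sub)
    list(n_maps = nrow(comp_sub),
         compression = comp_lme$coefficients,
         discrimination = disc_lme$coefficients,
         attention = data.frame(coefficient = att_reg$coefficient,
                                ci_lower = att_reg$ci[1L],
                                ci_upper = att_reg$ci[2L], p = att_reg$p))
  })
  for (nm in setdiff(names(stats_out), "n_maps")) {
    utils::write.table(stats_out[[nm]],
                       file.path(out, "stats", paste0(nm, "_lme.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  log_line("stats", "mixed models fitted")

  manifest <- list(
    package = "neurocompress",
    version = as.character(utils::packageVersion("neurocompress")),
    seed = config$seed, n_participants = config$n_participants,
    volume_dim = config$volume_dim, radius = config$radius,
    var_threshold = config$var_threshold,
    problem_subset = config$problem_subset,
    fit_sustain = config$fit_sustain,
    generating_params = unclass(config$generating_params),
    intrinsic_rank = config$spec$intrinsic_rank,
    category_separation = config$spec$category_separation,
    amplitude = config$spec$amplitude, noise_sd = config$spec$noise_sd
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(trials = trials, learning_curves = curves,
                 attention = attention, compression = compression,
                 discrimination = discrimination, stats = stats_out,
                 manifest = manifest))
}
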