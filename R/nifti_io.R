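#' Write a synthetic dataset to disk
#'
#' Lays out one participant's (or several participants') data in a simple
#' BIDS-flavored structure: per (participant, problem) an events TSV with
#' columns `onset`, `duration`, `trial_type`, `stimulus`, `response`,
#' `correct` plus bookkeeping columns; per (participant, problem, run) a 4-D
#' NIfTI beta series (one volume per trial); a shared 3-D mask; and a JSON
#' config snapshot.
#'
#' @param dir Output directory (created if needed).
#' @param trials Trial table (any number of participants).
#' @param betas Named list of [beta_series()] objects per participant:
#'   `betas[[participant_id]][[paste0(problem, "_run", run)]]`.
#' @param mask Logical 3-D array shared by all beta series.
#' @param config List serialized to `config.json`.
#' @param affine 4 x 4 affine stored in the NIfTI headers.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dir, trials, betas, mask, config = list(),
                          affine = diag(4)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  written <- character(0)

  mask_img <- nifti_with_affine(array(as.numeric(mask), dim = dim(mask)),
                                affine)
  mask_file <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(mask_img, mask_file, datatype = "uint8")
  written <- c(written, mask_file)

  for (pid in unique(trials$participant_id)) {
    for (problem in intersect(problem_levels(), trials$problem)) {
      sel <- trials$participant_id == pid & trials$problem == problem
      if (!any(sel)) next
      tr <- trials[sel, , drop = FALSE]
      tr <- tr[order(tr$run, tr$trial_index), , drop = FALSE]
      ev <- data.frame(
        onset = tr$onset_s, duration = tr$stim_duration_s,
        trial_type = "stimulus", stimulus = tr$stimulus_code,
        response = tr$response, correct = tr$correct,
        true_class = tr$true_class, run = tr$run,
        trial_index = tr$trial_index,
        feedback_onset = tr$feedback_onset_s,
        feedback_duration = tr$feedback_duration_s,
        problem_order_idx = tr$problem_order_idx
      )
      f <- file.path(dir, sprintf("%s_problem-%s_events.tsv", pid, problem))
      utils::write.table(ev, f, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
    for (key in names(betas[[pid]])) {
      bs <- betas[[pid]][[key]]
      vol <- array(0, dim = c(dim(bs$mask), nrow(bs$betas)))
      vox <- which(bs$mask)
      n_slice <- prod(dim(bs$mask))
      for (t in seq_len(nrow(bs$betas))) {
        vol[vox + (t - 1L) * n_slice] <- bs$betas[t, ]
      }
      f <- file.path(dir, sprintf("%s_problem-%s_beta.nii.gz", pid,
                                  sub("_run", "_run-", key)))
      RNifti::writeNifti(nifti_with_affine(vol, affine), f,
                         datatype = "double")
      written <- c(written, f)
    }
  }

  cfg_file <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, cfg_file)
  invisible(written)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `trials` (row-bound events tables), `betas` (nested
#'   list of [beta_series()] per participant), `mask`, and `config`.
#' @export
read_dataset <- function(dir) {
  mask_file <- file.path(dir, "mask.nii.gz")
  if (!file.exists(mask_file)) stop("no mask.nii.gz in ", dir)
  mask_arr <- as.array(RNifti::readNifti(mask_file))
  mask <- array(mask_arr > 0, dim = dim(mask_arr))
  vox <- which(mask)

  ev_files <- list.files(dir, pattern = "_events\\.tsv$", full.names = TRUE)
  trials_list <- lapply(ev_files, function(f) {
    base <- sub("_events\\.tsv$", "", basename(f))
    pid <- sub("_problem-.*$", "", base)
    problem <- sub("^.*_problem-", "", base)
    ev <- utils::read.table(f, sep = "\t", header = TRUE,
                            colClasses = c(stimulus = "character"))
    data.frame(
      participant_id = pid, problem = problem,
      problem_order_idx = ev$problem_order_idx, run = ev$run,
      trial_index = ev$trial_index, stimulus_code = ev$stimulus,
      onset_s = ev$onset, stim_duration_s = ev$duration,
      feedback_onset_s = ev$feedback_onset,
      feedback_duration_s = ev$feedback_duration,
      true_class = ev$true_class, response = ev$response,
      correct = ev$correct, stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, trials_list)

  beta_files <- list.files(dir, pattern = "_beta\\.nii\\.gz$",
                           full.names = TRUE)
  betas <- list()
  for (f in beta_files) {
    base <- sub("_beta\\.nii\\.gz$", "", basename(f))
    pid <- sub("_problem-.*$", "", base)
    rest <- sub("^.*_problem-", "", base)
    problem <- sub("_run-.*$", "", rest)
    run <- as.integer(sub("^.*_run-", "", rest))
    vol <- as.array(RNifti::readNifti(f))
    n_trial <- dim(vol)[4L]
    mat <- matrix(NA_real_, n_trial, length(vox))
    n_slice <- prod(dim(mask))
    for (t in seq_len(n_trial)) {
      mat[t, ] <- vol[vox + (t - 1L) * n_slice]
    }
    betas[[pid]][[paste(problem, run, sep = "_run")]] <- beta_series(
      mat, mask, meta = list(participant_id = pid, problem = problem,
                             run = run)
    )
  }

  cfg_file <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_file)) jsonlite::read_json(cfg_file) else list()
  list(trials = trials, betas = betas, mask = mask, config = config)
}

#' Write a 3-D map (e.g. compression or t map) as NIfTI
#'
#' @param map 3-D numeric array.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 affine.
#' @return Invisibly, `file`.
#' @export
write_map_nifti <- function(map, file, affine = diag(4)) {
  RNifti::writeNifti(nifti_with_affine(map, affine), file,
                     datatype = "double")
  invisible(file)
}

nifti_with_affine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}
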