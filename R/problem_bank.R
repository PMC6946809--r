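#' Build the three-problem stimulus bank
#'
#' The learning task uses eight stimuli formed by all combinations of three
#' binary feature attributes, classified into categories A and B under three
#' rules of increasing complexity: a unidimensional rule on attribute 1
#' ("low"), the exclusive-or of attributes 2 and 3 ("medium"), and the
#' three-way parity rule ("high", odd parity -> A). The same eight stimuli are
#' reused across all three problems; only the goal changes.
#'
#' Physical stimulus features can be randomly permuted onto the abstract
#' attributes, emulating per-participant counterbalancing. The permutation is
#' fixed across the three problems within a participant.
#'
#' @param seed Integer seed used when `randomize_feature_mapping` is `TRUE`.
#' @param randomize_feature_mapping Draw a seeded permutation mapping physical
#'   features to abstract attributes; `FALSE` gives the identity mapping.
#' @return An object of class `problem_bank`: a list with `stimuli` (8 x 3
#'   binary matrix, rows named by their bit codes), `class_map` (data frame
#'   with columns `code`, `low`, `medium`, `high`), and
#'   `feature_to_attribute` (integer permutation of 1:3).
#' @examples
#' bank <- make_problem_bank()
#' stimulus_class(bank, "000", "low")   # "A"
#' stimulus_class(bank, "111", "high")  # "A"
#' @export
make_problem_bank <- function(seed = 1L, randomize_feature_mapping = FALSE) {
  stimuli <- as.matrix(expand.grid(a3 = 0:1, a2 = 0:1, a1 = 0:1))[, 3:1]
  colnames(stimuli) <- c("attr1", "attr2", "attr3")
  codes <- apply(stimuli, 1L, paste, collapse = "")
  rownames(stimuli) <- codes

  low <- ifelse(stimuli[, 1L] == 0L, "A", "B")
  medium <- ifelse(xor(stimuli[, 2L] == 1L, stimuli[, 3L] == 1L), "B", "A")
  parity <- rowSums(stimuli) %% 2L
  high <- ifelse(parity == 1L, "A", "B")

  perm <- 1:3
  if (randomize_feature_mapping) {
    perm <- with_seed(seed, sample.int(3L))
  }

  structure(
    list(
      stimuli = stimuli,
      class_map = data.frame(
        code = codes, low = unname(low), medium = unname(medium),
        high = unname(high), stringsAsFactors = FALSE
      ),
      feature_to_attribute = perm
    ),
    class = "problem_bank"
  )
}

#' Look up the category of a stimulus under one problem
#'
#' @param bank A `problem_bank`.
#' @param code Character vector of 3-bit stimulus codes (e.g. `"010"`).
#' @param problem One of `"low"`, `"medium"`, `"high"`.
#' @return Character vector of `"A"`/`"B"` labels.
#' @export
stimulus_class <- function(bank, code, problem = c("low", "medium", "high")) {
  problem <- match.arg(problem)
  idx <- match(code, bank$class_map$code)
  if (anyNA(idx)) {
    stop("unknown stimulus code(s): ", paste(code[is.na(idx)], collapse = ", "))
  }
  bank$class_map[[problem]][idx]
}

#' @export
print.problem_bank <- function(x, ...) {
  cat("Problem bank: 8 stimuli x 3 binary attributes\n")
  cat("feature -> attribute mapping:", paste(x$feature_to_attribute, collapse = " "), "\n")
  print(x$class_map, row.names = FALSE)
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

problem_levels <- function() c("low", "medium", "high")

problem_complexity <- function(problem) {
  match(problem, problem_levels())
}
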