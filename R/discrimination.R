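#' PC-loading category discrimination
#'
#' Quantifies how much the retained principal components separate the two
#' categories: for each of the `k` PCs from the compression analysis, the
#' absolute difference between the mean trial loadings (projection scores) of
#' category A and category B trials is weighted by that PC's explained
#' variance ratio; the weighted differences are summed. A score of 0 means
#' both categories load identically on every retained PC; larger scores mean
#' category structure drives the compression solution.
#'
#' @param comp A `compression_result` from [pca_k()].
#' @param labels Per-trial category labels (`"A"`/`"B"`), length `n`; both
#'   categories must be present.
#' @return A `discrimination_result` list: `score`, `per_pc` (the k weighted
#'   contributions), `k`, and the label table.
#' @export
pc_category_discrimination <- function(comp, labels) {
  stopifnot(inherits(comp, "compression_result"))
  labels <- as.character(labels)
  if (length(labels) != comp$n) {
    stop("labels must have one entry per trial (", comp$n, ")")
  }
  if (!all(labels %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  if (length(unique(labels)) < 2L) {
    stop("both categories must be present to compute discrimination")
  }
  scores <- comp$pc_scores
  evr <- comp$explained_variance_ratio[seq_len(comp$k)]
  mean_a <- colMeans(scores[labels == "A", , drop = FALSE])
  mean_b <- colMeans(scores[labels == "B", , drop = FALSE])
  per_pc <- evr * abs(mean_a - mean_b)
  structure(
    list(score = sum(per_pc), per_pc = per_pc, k = comp$k,
         labels = table(labels)),
    class = "discrimination_result"
  )
}

#' Permutation null distribution for the discrimination score
#'
#' Recomputes the discrimination score under seeded label permutations that
#' preserve the class counts, yielding an empirical null and the p-value
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @inheritParams pc_category_discrimination
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `observed`, `null` (length `n_perm`), and `p`.
#' @export
permutation_null <- function(comp, labels, n_perm = 999L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  observed <- pc_category_discrimination(comp, labels)$score
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pc_category_discrimination(comp, sample(labels))$score
  }, numeric(1L)))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}
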