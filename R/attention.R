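#' Normalize attention tunings to a probability distribution
#'
#' Divides the non-negative tunings `lambda_i` by their sum, yielding the
#' probability that attention is directed to each stimulus dimension.
#'
#' @param lambdas Numeric vector of non-negative tunings, not all zero.
#' @return Numeric vector summing to 1.
#' @export
normalize_attention <- function(lambdas) {
  if (any(lambdas < 0)) stop("attention tunings must be non-negative")
  s <- sum(lambdas)
  if (s <= 0) stop("attention tunings must not all be zero")
  lambdas / s
}

#' Shannon entropy of an attention distribution (bits)
#'
#' `-sum a_i log2 a_i` with the `0 * log 0 = 0` convention. High entropy
#' means attention is dispersed across dimensions; zero entropy means it is
#' concentrated on one.
#'
#' @param a Normalized attention weights (non-negative, summing to 1).
#' @return Entropy in bits.
#' @export
attention_entropy <- function(a) {
  nz <- a > 0
  -sum(a[nz] * log2(a[nz]))
}

#' Attention-compression index
#'
#' Entropy scaled by its maximum for the number of dimensions and subtracted
#' from 1: `1 - entropy(a) / log2(length(a))`. Ranges from 0 (unselective,
#' uniform weights) to 1 (fully selective, one-hot weights), aligning the
#' attentional measure with the neural compression score.
#'
#' @param a Normalized attention weights.
#' @return Scalar in `[0, 1]`.
#' @examples
#' attention_compression(c(1, 1, 1) / 3)  # 0
#' attention_compression(c(1, 0, 0))      # 1
#' @export
attention_compression <- function(a) {
  1 - attention_entropy(a) / log2(length(a))
}

#' Block-averaged attention compression from a tuning trajectory
#'
#' Computes the per-trial attention-compression index from the trial-by-trial
#' tunings and averages it within each learning block (functional run),
#' separately per problem.
#'
#' @param trajectory Data frame from [attention_trajectory()] (columns
#'   `participant_id`, `problem`, `block`, `lambda1..lambda3`).
#' @return Data frame with one row per (participant, problem, block) and an
#'   `attention_compression` column.
#' @export
blockwise_attention_compression <- function(trajectory) {
  needed <- c("participant_id", "problem", "block",
              "lambda1", "lambda2", "lambda3")
  missing <- setdiff(needed, names(trajectory))
  if (length(missing)) {
    stop("trajectory lacks column(s): ", paste(missing, collapse = ", "))
  }
  lam <- as.matrix(trajectory[, c("lambda1", "lambda2", "lambda3")])
  per_trial <- apply(lam, 1L, function(x) {
    attention_compression(normalize_attention(x))
  })
  agg <- aggregate(
    per_trial,
    by = list(participant_id = trajectory$participant_id,
              problem = trajectory$problem, block = trajectory$block),
    FUN = mean
  )
  names(agg)[4L] <- "attention_compression"
  agg[order(agg$participant_id, agg$problem, agg$block), , drop = FALSE]
}
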