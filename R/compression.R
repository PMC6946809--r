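#' PCA compression of a trial-pattern matrix
#'
#' Mean-centers the patterns per voxel (no variance scaling), takes the
#' singular value decomposition, and finds the smallest number of principal
#' components `k` whose cumulative explained-variance ratio reaches
#' `var_threshold`. The compression score is `1 - k/n`, where `n` is the
#' number of trial patterns: 0 means no dimensionality reduction is possible
#' (`k = n`), values near `1 - 1/n` mean the patterns occupy a single
#' dimension.
#'
#' @param patterns Trials x voxels numeric matrix (`n >= 2` rows).
#' @param var_threshold Cumulative explained-variance criterion (default 0.9).
#' @return A `compression_result` list: `k`, `n`, `compression`,
#'   `explained_variance_ratio` (non-increasing, summing to 1), `pc_scores`
#'   (trials x k projections onto unit PC axes, retained for category
#'   discrimination), and `zero_variance` flag.
#' @examples
#' m <- tcrossprod(rnorm(32), rnorm(50))  # rank 1
#' pca_k(m)$compression                   # 1 - 1/32
#' @export
pca_k <- function(patterns, var_threshold = 0.9) {
  n <- nrow(patterns)
  if (is.null(n) || n < 2L) stop("patterns must have at least 2 rows")
  if (var_threshold <= 0 || var_threshold > 1) {
    stop("var_threshold must be in (0, 1]")
  }
  centered <- sweep(patterns, 2L, colMeans(patterns))
  sv <- svd(centered, nu = n, nv = 0L)
  var_comp <- sv$d^2
  total <- sum(var_comp)
  zero_variance <- total <= 0
  if (zero_variance) {
    warning("zero-variance pattern matrix; k = 1 by convention")
    k <- 1L
    evr <- rep(0, length(var_comp))
  } else {
    evr <- var_comp / total
    k <- which(cumsum(evr) >= var_threshold - 1e-12)[1L]
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = n)
  structure(
    list(k = as.integer(k), n = as.integer(n),
         compression = 1 - k / n,
         explained_variance_ratio = evr,
         pc_scores = scores,
         zero_variance = zero_variance),
    class = "compression_result"
  )
}

#' Integer offsets of a voxel-radius searchlight sphere
#'
#' All integer `(dx, dy, dz)` with Euclidean norm at most `radius`, center
#' included. At the default radius of 4 voxels the sphere has 257 offsets.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @return Integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius = 4) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  out <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Searchlight map of PCA compression
#'
#' Moves a voxel-radius sphere over every in-mask voxel of a beta series,
#' truncates it to in-mask voxels, and computes [pca_k()] compression on the
#' trials x sphere matrix, assigning the score to the center voxel. Spheres
#' smaller than `min_sphere_voxels` are skipped (`NA`).
#'
#' @param bs A [beta_series()].
#' @param radius Sphere radius in voxels (default 4).
#' @param var_threshold Explained-variance criterion (default 0.9).
#' @param min_sphere_voxels Minimum in-mask sphere size (default 10).
#' @return A `compression_map` list: 3-D arrays `compression`, `k` and
#'   `sphere_size` (`NA`/0 outside the mask), the `mask`, and the call
#'   parameters.
#' @export
searchlight_compression <- function(bs, radius = 4, var_threshold = 0.9,
                                    min_sphere_voxels = 10L) {
  stopifnot(inherits(bs, "beta_series"))
  dims <- dim(bs$mask)
  vox <- which(bs$mask)
  if (length(vox) == 0L) stop("mask contains no voxels")
  xyz <- arrayInd(vox, dims) - 1L
  res <- .searchlight_compression_cpp(
    bs$betas, xyz, as.integer(dims), sphere_offsets(radius),
    var_threshold, as.integer(min_sphere_voxels)
  )
  to_vol <- function(values, fill = NA_real_) {
    v <- array(fill, dim = dims)
    v[vox] <- values
    v
  }
  structure(
    list(compression = to_vol(res$compression),
         k = to_vol(res$k, NA_integer_),
         sphere_size = to_vol(res$sphere_size, 0L),
         mask = bs$mask, radius = radius, var_threshold = var_threshold,
         min_sphere_voxels = min_sphere_voxels, meta = bs$meta),
    class = "compression_map"
  )
}

#' Mean activation over a region of interest
#'
#' Mean of the beta estimates over ROI voxels and trials — the univariate
#' control quantity used to check that compression effects are not plain
#' activation differences.
#'
#' @param bs A [beta_series()].
#' @param roi_mask Logical 3-D array; must lie within the beta-series mask.
#' @return Scalar mean activation.
#' @export
roi_mean_activation <- function(bs, roi_mask) {
  stopifnot(inherits(bs, "beta_series"))
  if (!identical(dim(roi_mask), dim(bs$mask))) {
    stop("roi_mask dimensions must match the beta-series mask")
  }
  if (!any(roi_mask)) stop("roi_mask is empty")
  if (any(roi_mask & !bs$mask)) {
    stop("roi_mask includes voxels outside the beta-series mask")
  }
  cols <- match(which(roi_mask), which(bs$mask))
  mean(bs$betas[, cols, drop = FALSE])
}
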