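# A small balanced panel (participant x problem x block) with a planted
# outcome model.
make_panel <- function(n_sub = 12L, interaction = 0, block_eff = 0,
                       complexity_eff = 0, noise = 0.05, seed = 1L,
                       re_sd = 0.05) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("s%02d", seq_len(n_sub)),
                   complexity = 1:3, block = 1:4,
                   stringsAsFactors = FALSE)
  re <- rnorm(n_sub, sd = re_sd)
  g$accuracy <- runif(nrow(g), 0.5, 1)
  g$y <- 0.5 + re[match(g$participant_id, unique(g$participant_id))] +
    block_eff * g$block + complexity_eff * g$complexity +
    interaction * g$block * g$complexity + rnorm(nrow(g), sd = noise)
  g
}

test_that("the mixed model recovers planted block-by-complexity effects", {
  panel <- make_panel(interaction = -0.04, block_eff = 0.1, seed = 2)
  fit <- block_complexity_lme(panel, outcome = "y")
  co <- fit$coefficients
  inter <- co[co$term == "block:complexity", ]
  expect_lt(inter$estimate, 0)
  expect_lt(inter$p, 0.001)
  expect_equal(inter$estimate, -0.04, tolerance = 0.05)
  expect_error(block_complexity_lme(panel[, -3], outcome = "y"),
               "lacks column")
})

test_that("voxel-wise interaction maps recover planted signs and stay calibrated", {
  n_vox <- 60L
  panel <- make_panel(seed = 3)
  # null outcome at every voxel: exceedances of |t| > 3.29 stay near the
  # nominal two-sided 0.001 rate
  vals <- sapply(seq_len(n_vox), function(v) {
    make_panel(seed = 100 + v)$y
  })
  sm <- voxelwise_interaction_map(vals, panel)
  exceed <- sum(abs(sm$t) > 3.29, na.rm = TRUE)
  expect_lte(exceed, 3L)
  # planted negative interaction at a subset of voxels
  planted <- vals
  planted[, 1:5] <- planted[, 1:5] - 0.05 * panel$block * panel$complexity
  sm2 <- voxelwise_interaction_map(planted, panel)
  expect_true(all(sm2$t[1:5] < 0))
  expect_true(all(sm2$p[1:5] < 0.001))
  # relabeling participants jointly leaves the fit unchanged (random
  # intercept exchangeability)
  relab <- panel
  relab$participant_id <- sprintf("r%02d",
                                  match(panel$participant_id,
                                        unique(panel$participant_id)))
  sm3 <- voxelwise_interaction_map(planted[, 1:5, drop = FALSE], relab)
  expect_equal(sm3$t, sm2$t[1:5], tolerance = 1e-6)
})

test_that("cluster extraction matches an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  dims <- c(10L, 10L, 10L)
  offs <- neurocompress:::connectivity_offsets(18L)
  set.seed(4)
  for (i in 1:30) {
    t_map <- array(rnorm(prod(dims)), dim = dims)
    tab <- cluster_extract(t_map, t_threshold = 1.5, extent = 1L)
    supra <- which(abs(t_map) >= 1.5)
    # oracle: connected components of the supra-threshold adjacency graph
    xyz <- arrayInd(supra, dims)
    key <- match(supra, supra)
    edges <- list()
    for (j in seq_along(supra)) {
      nb <- sweep(offs, 2L, xyz[j, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      hit <- match(lin, supra)
      hit <- hit[!is.na(hit) & hit > j]
      if (length(hit)) edges[[length(edges) + 1L]] <- rbind(j, hit)
    }
    g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
    if (length(edges)) {
      g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
    }
    comp_sizes <- sort(as.integer(table(igraph::components(g)$membership)),
                       decreasing = TRUE)
    expect_identical(sort(tab$size, decreasing = TRUE), comp_sizes)
  }
})

test_that("cluster extraction handles planted blocks and extent thresholds", {
  t_map <- array(0, dim = c(12, 12, 12))
  t_map[4:8, 4:8, 4:8] <- 5
  tab <- cluster_extract(t_map, t_threshold = 3, extent = 1)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$size, 125L)
  expect_identical(tab$peak_t, 5)
  expect_identical(nrow(cluster_extract(t_map, t_threshold = 3,
                                        extent = 200)), 0L)
  # voxel_p + df conversion: p = 0.001 two-sided at large df ~ |t| > 3.29
  t_map2 <- array(0, dim = c(5, 5, 5))
  t_map2[3, 3, 3] <- 3.3
  expect_identical(nrow(cluster_extract(t_map2, voxel_p = 0.001, df = 1e6,
                                        extent = 1)), 1L)
  expect_identical(nrow(cluster_extract(t_map2, voxel_p = 0.0001, df = 1e6,
                                        extent = 1)), 0L)
})

test_that("behavioral regression finds learning and ignores shuffled accuracy", {
  trials <- do.call(rbind, lapply(1:6, function(i) {
    tr <- make_learner_trials(seed = 600 + i)
    tr$participant_id <- sprintf("s%02d", i)
    tr
  }))
  fit <- behavioral_learning_regression(trials)
  rep_row <- fit$tests[fit$tests$term == "repetition", ]
  expect_gt(rep_row$chisq, 10)
  expect_lt(rep_row$p, 0.001)
  # shuffling accuracy destroys the repetition effect
  shuffled <- trials
  set.seed(5)
  shuffled$correct <- sample(shuffled$correct)
  fit2 <- behavioral_learning_regression(shuffled)
  rep2 <- fit2$tests[fit2$tests$term == "repetition", ]
  expect_lt(rep2$chisq, qchisq(0.999, df = 1))
})

test_that("learning curves aggregate 16-trial blocks", {
  tr <- make_learner_trials(seed = 701)
  curves <- learning_curves(tr)
  # 384 trials / 16 = 24 points, 8 per problem
  expect_identical(nrow(curves), 24L)
  expect_true(all(table(curves$problem) == 8L))
  all_right <- tr
  all_right$correct <- TRUE
  expect_true(all(learning_curves(all_right)$accuracy == 1))
  alternating <- tr
  alternating$correct <- rep(c(TRUE, FALSE), nrow(tr) / 2)
  expect_true(all(learning_curves(alternating)$accuracy == 0.5))
  expect_error(learning_curves(tr, block_size = 7L), "divide")
})

test_that("the neural-to-attention regression recovers a planted coefficient", {
  truth <- 0.2
  covered <- logical(50)
  for (i in 1:50) {
    set.seed(900 + i)
    g <- expand.grid(participant_id = sprintf("s%02d", 1:23),
                     problem = c("low", "medium", "high"), block = 1:4,
                     stringsAsFactors = FALSE)
    g$order <- match(g$problem, c("high", "low", "medium"))
    g$accuracy <- runif(nrow(g), 0.5, 1)
    g$neural_compression <- runif(nrow(g), 0.3, 0.9)
    re <- rnorm(23, sd = 0.03)
    att <- data.frame(
      participant_id = g$participant_id, problem = g$problem,
      block = g$block,
      attention_compression = 0.1 + truth * g$neural_compression +
        re[match(g$participant_id, unique(g$participant_id))] +
        rnorm(nrow(g), sd = 0.05)
    )
    res <- compression_attention_regression(g, att)
    covered[i] <- res$ci[1] <= truth && truth <= res$ci[2]
  }
  expect_gte(mean(covered), 0.9)
  # duplicating every row leaves the point estimate unchanged
  set.seed(901)
  g <- expand.grid(participant_id = sprintf("s%02d", 1:10),
                   problem = c("low", "medium", "high"), block = 1:4,
                   stringsAsFactors = FALSE)
  g$order <- 1
  g$accuracy <- runif(nrow(g))
  g$neural_compression <- runif(nrow(g))
  att <- data.frame(participant_id = g$participant_id, problem = g$problem,
                    block = g$block,
                    attention_compression = 0.2 * g$neural_compression +
                      rnorm(nrow(g), sd = 0.02))
  r1 <- compression_attention_regression(g, att)
  r2 <- compression_attention_regression(rbind(g, g), rbind(att, att))
  expect_equal(r2$coefficient, r1$coefficient, tolerance = 5e-3)
  expect_error(compression_attention_regression(g, att[0, ]), "share no")
})
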