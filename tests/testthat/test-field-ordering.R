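test_that("covariance ranks order partners by covariance magnitude with index tie-breaks", {
  # direct oracle on a hand-built score row: |cov| 0.9 > 0.5 > 0.1
  scores <- rbind(c(NA, 0.9, 0.1, 0.5),
                  c(0.9, NA, 0.3, 0.2),
                  c(0.1, 0.3, NA, 0.7),
                  c(0.5, 0.2, 0.7, NA))
  diag(scores) <- 1
  rm <- tab2img:::rank_matrix_from_scores(abs(scores))
  expect_equal(rm$ranks[1, ], c(NA, 1L, 3L, 2L))
  # all-equal off-diagonals rank purely by the lower-index tie rule
  flat <- tab2img:::rank_matrix_from_scores(matrix(1, 4, 4))
  expect_equal(flat$ranks[2, ], c(1L, NA, 2L, 3L))
  expect_equal(flat$ranks[4, ], c(1L, 2L, 3L, NA))
  # two fields: the only partner is rank 1 on both rows
  two <- tab2img:::rank_matrix_from_scores(matrix(c(1, .2, .2, 1), 2))
  expect_equal(two$ranks, rbind(c(NA, 1L), c(1L, NA)), ignore_attr = TRUE)
  # every off-diagonal row is a permutation of 1..d-1
  set.seed(12)
  rnd <- covariance_rank_matrix(matrix(rnorm(200), 20, 10))
  for (i in 1:10)
    expect_setequal(rnd$ranks[i, -i], 1:9)
})

test_that("rank matrices are invariant to affine rescaling after min-max normalization", {
  set.seed(21)
  feats <- matrix(rnorm(300), 30, 10)
  ds1 <- minmax_normalize(tabular_dataset(feats, rep_len(0:1, 30)))
  rescaled <- sweep(sweep(feats, 2, runif(10, 0.5, 4), "*"), 2,
                    runif(10, -5, 5), "+")
  ds2 <- minmax_normalize(tabular_dataset(rescaled, rep_len(0:1, 30)))
  expect_equal(covariance_rank_matrix(ds1)$ranks,
               covariance_rank_matrix(ds2)$ranks)
})

test_that("path cost sums symmetrized adjacent ranks and is reversal-invariant", {
  inst <- known_rank_instance(4, seed = 3)
  rm <- inst$rank_matrix
  ord <- c(2L, 4L, 1L, 3L)
  expect_equal(path_cost(ord, rm), naive_path_cost(ord, rm$ranks))
  expect_equal(path_cost(rev(ord), rm), path_cost(ord, rm))
  # d = 2: single edge whichever direction
  two <- tab2img:::rank_matrix_from_scores(matrix(c(1, .2, .2, 1), 2))
  expect_equal(path_cost(1:2, two), 1)
  expect_equal(path_cost(2:1, two), 1)
})

test_that("brute force matches an independent full enumeration and breaks ties lexicographically", {
  for (seed in 1:6) {
    inst <- known_rank_instance(sample(4:6, 1), seed = seed)
    rm <- inst$rank_matrix
    d <- rm$d
    costs <- vapply(all_permutations(d), naive_path_cost,
                    numeric(1), ranks = rm$ranks)
    expect_equal(brute_force_order(rm)$cost, min(costs))
  }
  # all-ties instance (every symmetrized edge weight 1.5):
  # lexicographically smallest order wins
  flat <- structure(list(ranks = rbind(c(NA, 1L, 2L), c(2L, NA, 1L),
                                       c(1L, 2L, NA)),
                         derivation = NULL, d = 3L),
                    class = "rank_matrix")
  expect_equal(brute_force_order(flat)$order, 1:3)
  # d = 2 trivially returns the identity
  two <- tab2img:::rank_matrix_from_scores(matrix(c(1, .2, .2, 1), 2))
  expect_equal(brute_force_order(two)$order, 1:2)
  big <- tab2img:::rank_matrix_from_scores(matrix(1, 11, 11))
  expect_error(brute_force_order(big), "d > 10")
})

test_that("GA finds the exhaustive optimum on small instances, never beats identity's cost, and is seed-stable", {
  hits <- 0L
  for (seed in 1:20) {
    inst <- known_rank_instance(3L + (seed %% 6L), seed = 1000L + seed)
    got <- ga_order(inst$rank_matrix, ga_config(seed = seed))
    expect_lte(got$cost, inst$identity_cost)
    expect_gte(got$cost, inst$optimum$cost)
    if (got$cost == inst$optimum$cost) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # d = 2 is solved immediately
  two <- tab2img:::rank_matrix_from_scores(matrix(c(1, .2, .2, 1), 2))
  expect_equal(ga_order(two, ga_config(generations = 1, seed = 1))$cost, 1)
  # determinism
  inst <- known_rank_instance(7, seed = 5)
  a <- ga_order(inst$rank_matrix, ga_config(seed = 42))
  b <- ga_order(inst$rank_matrix, ga_config(seed = 42))
  expect_identical(a$order, b$order)
})

test_that("block-correlated data yields orderings that group blocks below an interleaved identity", {
  # interleave two strongly correlated blocks so the identity order is bad
  spec <- sim_spec(n = 2000, d = 6, separation = 0, block_correlation = 0.9,
                   n_blocks = 2, seed = 31)
  ds <- simulate_tabular(spec)
  interleave <- c(1L, 4L, 2L, 5L, 3L, 6L)
  shuffled <- tabular_dataset(ds$features[, interleave],
                              ds$labels)
  rm <- covariance_rank_matrix(shuffled)
  opt <- brute_force_order(rm)
  expect_lt(opt$cost, path_cost(1:6, rm))
  # the optimum keeps each original block contiguous
  orig <- interleave[opt$order]
  block <- (orig > 3L)
  expect_equal(sum(abs(diff(block))), 1)
})
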