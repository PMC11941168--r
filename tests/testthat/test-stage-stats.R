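test_that("constant genes are masked, not fatal", {
  x <- toy_expression(rbind(c(1, 1, 1), c(1, 2, 3), c(4, 1, 2)))
  st <- compute_stage_stats(x)
  expect_equal(unname(st$gene_sd[1]), 0)
  expect_true(st$mask[1])
  expect_equal(unname(st$abs_corr[1, 2]), 0)
  expect_equal(unname(st$abs_corr[2, 2]), 1)
})

test_that("perfectly proportional genes have |r| = 1", {
  x <- toy_expression(rbind(c(1, 2, 3), c(2, 4, 6)))
  st <- compute_stage_stats(x)
  expect_equal(unname(st$abs_corr[1, 2]), 1)
})

test_that("sd and |r| match a direct evaluation of the defining formulas", {
  set.seed(77)
  V <- matrix(rnorm(20), 4, 5)
  st <- compute_stage_stats(toy_expression(V))
  for (i in 1:4) {
    mu <- sum(V[i, ]) / 5
    sd_direct <- sqrt(sum((V[i, ] - mu)^2) / 4)
    expect_equal(unname(st$gene_sd[i]), sd_direct, tolerance = 1e-12)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- V[i, ] - mean(V[i, ]); xj <- V[j, ] - mean(V[j, ])
    r_direct <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(unname(st$abs_corr[i, j]), abs(r_direct), tolerance = 1e-12)
  }
})

test_that("prefilter keeps genes by max-to-reference sd fold", {
  mk_series <- function(sds_by_stage) {
    # three stages, five samples; gene g has sd pattern sds_by_stage[g, t]
    stages <- lapply(1:ncol(sds_by_stage), function(t) {
      base <- c(-2, -1, 0, 1, 2) / sd(c(-2, -1, 0, 1, 2))
      V <- sds_by_stage[, t, drop = FALSE] %*% base
      toy_expression(V, sprintf("st%d", t))
    })
    stage_series(stages)
  }
  ser <- mk_series(cbind(c(1, 1, 0), c(1, 1, 0), c(3, 1.2, 0)))
  # vacuous threshold keeps every gene with nonzero sd
  expect_identical(prefilter_candidates(ser, sd_fold_min = 1), c(1L, 2L))
  # fold 2: gene 1 has max/ref = 3 >= 2, gene 2 only 1.2
  expect_equal(prefilter_candidates(ser, sd_fold_min = 2), 1L)
  # zero reference sd, positive later sd: kept at any threshold
  ser2 <- mk_series(cbind(c(0, 1), c(2, 1), c(2, 1)))
  expect_true(1L %in% prefilter_candidates(ser2, sd_fold_min = 5))
})

test_that("clustering recovers a perfectly correlated pair", {
  x <- toy_expression(rbind(c(1, 2, 3), c(2, 4, 6), c(5, -1, 3)))
  st <- compute_stage_stats(x)
  cl <- cluster_members(st, 1:3, corr_link_min = 0.8)
  expect_length(cl, 1)
  expect_equal(cl[[1]], c(1L, 2L))
})

test_that("clustering recovers planted blocks, verified by a graph oracle", {
  x <- two_block_fixture()
  st <- compute_stage_stats(x)
  cl <- cluster_members(st, 1:8, corr_link_min = 0.6)
  # independent oracle: components of the |r| >= 0.6 threshold graph
  comps <- threshold_components(st$abs_corr, 0.6)
  comps <- comps[lengths(comps) >= 2]
  expect_length(cl, 2)
  expect_setequal(lapply(cl, sort), lapply(comps, sort))
  expect_setequal(cl, list(1:3, 4:6))
})

test_that("clustering returns an empty list when nothing links", {
  set.seed(42)
  x <- toy_expression(matrix(rnorm(4 * 100), 4))
  st <- compute_stage_stats(x)
  expect_equal(cluster_members(st, 1:4, corr_link_min = 0.99), list())
  # all-masked candidates
  x2 <- toy_expression(matrix(1, 3, 4))
  st2 <- compute_stage_stats(x2)
  expect_equal(cluster_members(st2, 1:3, corr_link_min = 0.5), list())
})

test_that("composite index equals a direct evaluation of its formula", {
  set.seed(9)
  V <- rbind(matrix(rnorm(15), 3, 5), matrix(rnorm(10), 2, 5))
  st <- compute_stage_stats(toy_expression(V))
  ci <- composite_index(st, 1:3, eps = 1e-6)
  R <- st$abs_corr
  sd_in <- mean(st$gene_sd[1:3])
  r_in <- mean(c(R[1, 2], R[1, 3], R[2, 3]))
  r_out <- mean(R[1:3, 4:5])
  expect_equal(ci$index, sd_in * r_in / r_out, tolerance = 1e-12)
  expect_equal(ci$sd_in, sd_in, tolerance = 1e-12)
  expect_equal(ci$r_in, r_in, tolerance = 1e-12)
  expect_equal(ci$r_out, r_out, tolerance = 1e-12)
})

test_that("composite index degrades safely at the edges", {
  # all-constant members: zero numerator, index 0
  x <- toy_expression(rbind(c(1, 1, 1), c(2, 2, 2), c(1, 3, 2)))
  st <- compute_stage_stats(x)
  expect_equal(composite_index(st, 1:2)$index, 0)
  # r_out exactly 0 (outsider constant -> masked correlation): eps guard
  x2 <- toy_expression(rbind(c(1, 2, 3), c(2, 4.1, 5.9), c(7, 7, 7)))
  st2 <- compute_stage_stats(x2)
  ci <- composite_index(st2, 1:2, eps = 1e-6)
  expect_true(is.finite(ci$index))
  expect_equal(ci$index, ci$sd_in * ci$r_in / 1e-6, tolerance = 1e-12)
  expect_error(composite_index(st2, 1L), class = "dnbscreen_invalid_config")
})

test_that("composite index scales linearly with the expression scale", {
  set.seed(15)
  V <- matrix(rnorm(30), 6, 5)
  st1 <- compute_stage_stats(toy_expression(V))
  st2 <- compute_stage_stats(toy_expression(V * 3.7))
  i1 <- composite_index(st1, 1:3)
  i2 <- composite_index(st2, 1:3)
  expect_equal(i2$index, 3.7 * i1$index, tolerance = 1e-10)
  expect_equal(i2$r_in, i1$r_in, tolerance = 1e-12)
})

test_that("detection is equivariant under gene permutation", {
  mod <- build_network(60, 8, seed = 4)
  ser <- generate_stage_series(mod, 6, seed = 10)
  cfg <- dnb_config(min_module_size = 4, corr_link_min = 0.8)
  res <- detect_predisease(ser, cfg)
  set.seed(2)
  perm <- sample.int(60)
  stages_p <- lapply(ser$stages, function(s) {
    expression_matrix(s$values[perm, ], s$gene_ids[perm], s$sample_ids,
                      s$stage_label)
  })
  res_p <- detect_predisease(stage_series(stages_p), cfg)
  expect_equal(res_p$composite_index_by_stage, res$composite_index_by_stage,
               tolerance = 1e-12)
  expect_setequal(res_p$members, res$members)
  expect_identical(res_p$predisease_stage, res$predisease_stage)
})
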