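ann_path <- system.file("extdata", "tsod_top10_annotation.tsv",
                        package = "dnbscreen")

test_that("the biotype filter reduces the published top-10 list to 8 genes", {
  ann <- read_annotation_tsv(ann_path)
  top10 <- ann$gene_id
  kept <- filter_by_biotype(top10, ann, excluded_biotypes = "lncRNA")
  expect_length(kept, 8)
  expect_setequal(setdiff(top10, kept), c("Rbakdn", "4930449C09Rik"))
  expect_identical(kept, setdiff(top10, c("Rbakdn", "4930449C09Rik")))
})

test_that("biotype filter edge cases behave as documented", {
  ann <- read_annotation_tsv(ann_path)
  expect_identical(filter_by_biotype(ann$gene_id, ann, character(0)),
                   ann$gene_id)
  lnc <- c("Rbakdn", "4930449C09Rik")
  expect_warning(out <- filter_by_biotype(lnc, ann, "lncRNA"),
                 class = "dnbscreen_empty_selection")
  expect_length(out, 0)
  expect_warning(kept <- filter_by_biotype(c("Cst9", "NotAGene"), ann),
                 class = "dnbscreen_missing_annotation")
  expect_identical(kept, c("Cst9", "NotAGene"))
  expect_warning(dropped <- filter_by_biotype(c("Cst9", "NotAGene"), ann,
                                              on_missing = "drop"),
                 class = "dnbscreen_missing_annotation")
  expect_identical(dropped, "Cst9")
})

test_that("zero-strength intervention is a bit-exact no-op", {
  mod <- build_network(30, 4, seed = 5)
  out <- simulate_intervention(mod, 0.9, mod$gene_ids[mod$dnb_genes], 0)
  expect_identical(out$total_var_before, out$total_var_after)
  expect_identical(out$leading_eig_before, out$leading_eig_after)
  expect_identical(out$dnb_var_before, out$dnb_var_after)
})

test_that("scalar-rate intervention matches the OU closed form", {
  # two independent genes with a = 0.5, sigma = 1: variance 1/(2a) = 1;
  # strength 0.5 doubles the rate and halves the variance to 0.5
  mod <- build_network(2, 1, intra_coupling = 0, seed = 1, noise_scale = 1)
  mod$drift_base <- diag(-0.5, 2)
  mod$drift_mod <- matrix(0, 2, 2)
  out <- simulate_intervention(mod, 0, 1L, 0.5)
  v_before <- out$total_var_before - 1  # subtract the untouched gene
  v_after <- out$total_var_after - 1
  expect_equal(v_before, 1.0, tolerance = 1e-12)
  expect_equal(v_after, 0.5, tolerance = 1e-12)
})

test_that("stabilizing top targets reduces fluctuation in the default model", {
  mod <- demo_model(seed = 42L)
  S <- stationary_covariance(mod, 0.95)
  r <- select_top(intervention_index(S, gene_ids = mod$gene_ids), 10)
  out <- simulate_intervention(mod, 0.95, r$selected, 0.5)
  expect_lt(out$total_var_after, out$total_var_before)
  expect_lte(out$leading_eig_after, out$leading_eig_before)
  expect_lt(out$dnb_var_after, out$dnb_var_before)
  # monotone in strength on a fixed grid
  vars <- vapply(c(0, 0.25, 0.5, 1), function(s) {
    simulate_intervention(mod, 0.95, r$selected, s)$total_var_after
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("post-intervention variance agrees with a trajectory-simulation oracle", {
  mod <- build_network(40, 10, seed = 21)
  S <- stationary_covariance(mod, 0.7)
  r <- select_top(intervention_index(S, gene_ids = mod$gene_ids), 10)
  out <- simulate_intervention(mod, 0.7, r$selected, 0.5)
  A2 <- drift_matrix(mod, 0.7)
  idx <- match(r$selected, mod$gene_ids)
  diag(A2)[idx] <- diag(A2)[idx] - 0.5
  S_em <- em_covariance(A2, mod$noise_cov, n_steps = 2e6, dt = 0.01,
                        seed = 5)
  expect_equal(out$total_var_after, sum(diag(S_em)), tolerance = 0.02)
})

test_that("intervention argument validation", {
  mod <- build_network(20, 3, seed = 2)
  expect_error(simulate_intervention(mod, 0.5, "nope", 0.5),
               class = "dnbscreen_invalid_input")
  expect_error(simulate_intervention(mod, 0.5, 25L, 0.5),
               class = "dnbscreen_invalid_input")
  expect_error(simulate_intervention(mod, 0.5, 1L, -1),
               class = "dnbscreen_invalid_config")
})

test_that("ranked targets beat random target sets on a planted model", {
  mod <- build_network(60, 8, seed = 11)
  S <- stationary_covariance(mod, 0.95)
  r <- intervention_index(S, gene_ids = mod$gene_ids)
  frac <- compare_to_random(mod, 0.95, r, k = 8, strength = 0.5,
                            n_draws = 50, seed = 7)
  expect_gte(as.numeric(frac), 0.95)
  # reproducible under the seed
  frac2 <- compare_to_random(mod, 0.95, r, k = 8, strength = 0.5,
                             n_draws = 50, seed = 7)
  expect_identical(as.numeric(frac), as.numeric(frac2))
})

test_that("comparison is degenerate when k spans all genes", {
  mod <- build_network(10, 2, seed = 3)
  r <- intervention_index(stationary_covariance(mod, 0.5),
                          gene_ids = mod$gene_ids)
  expect_warning(frac <- compare_to_random(mod, 0.5, r, k = 10,
                                           strength = 0.5, n_draws = 10,
                                           seed = 1),
                 class = "dnbscreen_degenerate_comparison")
  expect_equal(as.numeric(frac), 0.5)
})

test_that("a homogeneous network shows no targeting advantage", {
  # no module: intra_coupling 0 evaluated at the healthy baseline p = 0,
  # where the network is exactly homogeneous; every k-set ties and ties
  # count one half
  mod <- build_network(60, 8, intra_coupling = 0, seed = 11)
  x <- sample_stage(mod, 0, 8, seed = 4)
  r <- intervention_index(x)
  frac <- compare_to_random(mod, 0, r, k = 8, strength = 0.5,
                            n_draws = 50, seed = 7)
  expect_gte(as.numeric(frac), 0.3)
  expect_lte(as.numeric(frac), 0.7)
})
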