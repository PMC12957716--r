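test_that("pairwise matrices are symmetric with unit/zero diagonals", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 50, seed = 23))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  expect_equal(corr$r, t(corr$r), tolerance = 1e-12)
  expect_equal(corr$p, t(corr$p), tolerance = 1e-12)
  expect_equal(unname(diag(corr$r)), rep(1, 38))
  expect_equal(unname(diag(corr$p)), rep(0, 38))
  expect_equal(corr$df, 50 - 4 - 2)
})

test_that("matrix entries agree with looped single-pair calls", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 40, seed = 24))
  ch <- compute_change_table(co)
  cov <- cohort_covariates(co)
  corr <- pairwise_partial_correlations(ch, cov)
  Z <- as.matrix(cov[, c("age", "sex", "education", "apoe_e4_count")])
  ids <- subfield_ids()
  withr::with_seed(1, picks <- replicate(12, sample(ids, 2), simplify = FALSE))
  for (pk in picks) {
    single <- partial_correlation(ch[[pk[1]]], ch[[pk[2]]], Z)
    expect_equal(corr$r[pk[1], pk[2]], single$r, tolerance = 1e-12)
    expect_equal(corr$p[pk[1], pk[2]], single$p_value, tolerance = 1e-12)
  }
})

test_that("duplicated columns give r = 1 and errors name degenerate pairs", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 30, seed = 25))
  vb <- co$volumes_baseline
  vf <- co$volumes_followup
  # make two subfields identical in percentage change
  vf[, "CA3_body_R"] <- vb[, "CA3_body_R"] *
    (vf[, "CA3_body_L"] / vb[, "CA3_body_L"])
  dup <- make_cohort(vb, vf)
  corr <- pairwise_partial_correlations(compute_change_table(dup),
                                        cohort_covariates(dup))
  expect_equal(corr$r["CA3_body_L", "CA3_body_R"], 1, tolerance = 1e-10)
})

test_that("independent columns give small off-diagonal correlations", {
  co <- simulate_cohort(independent_noise_config(n_subjects = 2000,
                                                 seed = 26))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  off <- abs(corr$r[upper.tri(corr$r)])
  expect_lt(mean(off), 0.05)
})

test_that("thresholding keeps exactly the sub-alpha edges", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 60, seed = 27))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  net <- threshold_network(corr, alpha = 0.01)
  a <- net$adjacency
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(0, 38))
  ut <- upper.tri(a)
  expect_true(all((a[ut] != 0) == (corr$p[ut] < 0.01)))
  expect_true(all(a[ut][a[ut] != 0] ==
                    corr$r[ut][corr$p[ut] < 0.01]))
})

test_that("alpha = 1 yields the complete graph and alpha -> 0 empties it", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 40, seed = 28))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  full <- threshold_network(corr, alpha = 1)
  expect_equal(full$n_edges, 38 * 37 / 2)
  empty <- threshold_network(corr, alpha = 1e-300)
  expect_equal(empty$n_edges, 0)
  expect_error(threshold_network(corr, alpha = 0), "alpha")
})

test_that("edge sets are monotone in alpha", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 35, seed = 29))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  nets <- lapply(alphas, function(a) threshold_network(corr, a))
  for (i in seq_along(alphas)[-1]) {
    lo <- nets[[i - 1]]$adjacency != 0
    hi <- nets[[i]]$adjacency != 0
    expect_true(all(hi[lo]))  # smaller-alpha edges are a subset
    expect_gte(nets[[i]]$n_edges, nets[[i - 1]]$n_edges)
  }
})

test_that("planted correlated blocks survive thresholding with strong weights", {
  # two disjoint 4-subfield blocks with a strong shared factor each
  ids <- subfield_ids()
  L <- matrix(0, 38, 2, dimnames = list(ids, c("b1", "b2")))
  block1 <- ids[1:4]
  block2 <- ids[21:24]
  L[block1, 1] <- 4
  L[block2, 2] <- 4
  cfg <- cohort_config(258, seed = 30, factor_loadings = L, noise_sd = 1,
                       cognition_coupling = 0)
  co <- simulate_cohort(cfg)
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  net <- threshold_network(corr, alpha = 0.05)
  a <- net$adjacency
  for (blk in list(block1, block2)) {
    for (i in blk) for (j in setdiff(blk, i)) {
      expect_true(a[i, j] != 0)
      expect_gt(a[i, j], 0.9)
    }
  }
})

test_that("FDR and positive-only flags act as documented", {
  co <- simulate_cohort(independent_noise_config(n_subjects = 100,
                                                 seed = 31))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  plain <- threshold_network(corr, alpha = 0.05)
  fdr <- threshold_network(corr, alpha = 0.05, fdr = TRUE)
  expect_lte(fdr$n_edges, plain$n_edges)
  pos <- threshold_network(corr, alpha = 0.05, positive_only = TRUE)
  expect_true(all(pos$adjacency >= 0))
})

test_that("network tidiers report edges and summary", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 50, seed = 32))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  net <- threshold_network(corr, alpha = 0.05)
  edges <- tidy(net)
  expect_equal(nrow(edges), net$n_edges)
  expect_true(all(edges$weight != 0))
  g <- glance(net)
  expect_equal(g$n_edges, net$n_edges)
  expect_true(g$density <= 1)
  expect_error(threshold_network(list(r = matrix(c(1, .5, 0, 1), 2),
                                      p = matrix(0, 2, 2))), "symmetric")
})
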