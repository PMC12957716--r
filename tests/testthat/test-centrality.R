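star_graph <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  dimnames(A) <- list(paste0("V", 1:n), paste0("V", 1:n))
  A
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  dimnames(A) <- list(paste0("V", 1:n), paste0("V", 1:n))
  A
}

complete_graph <- function(n) {
  A <- 1 - diag(n)
  dimnames(A) <- list(paste0("V", 1:n), paste0("V", 1:n))
  A
}

test_that("closed forms: star, path and complete graphs", {
  s5 <- star_graph(5)
  expect_equal(unname(degree_centrality(s5)), c(4, 1, 1, 1, 1))
  expect_equal(unname(betweenness_centrality(s5)), c(choose(4, 2), 0, 0, 0, 0))
  expect_equal(unname(closeness_centrality(s5)), c(1, rep(4 / 7, 4)))
  ev <- eigenvector_centrality(s5)
  expect_equal(ev$lambda, 2, tolerance = 1e-10)  # sqrt(N - 1)
  expect_equal(unname(ev$vector[1] / ev$vector[2]), 2, tolerance = 1e-9)

  p3 <- path_graph(3)
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))

  k38 <- complete_graph(38)
  expect_equal(unname(degree_centrality(k38)), rep(37L, 38))
  expect_equal(unname(betweenness_centrality(k38)), rep(0, 38))
  expect_equal(unname(closeness_centrality(k38)), rep(1, 38))
  k4 <- complete_graph(4)
  ev4 <- eigenvector_centrality(k4)
  expect_equal(unname(ev4$vector), rep(0.25, 4), tolerance = 1e-10)
  expect_equal(ev4$lambda, 3, tolerance = 1e-10)
})

test_that("all four metrics match brute-force oracles on random graphs", {
  withr::with_seed(77, {
    for (rep in 1:150) {
      n <- sample(3:8, 1)
      A <- random_graph(n, p = runif(1, 0.2, 0.8))
      expect_equal(unname(degree_centrality(A)),
                   unname(rowSums(A != 0)))
      expect_equal(unname(betweenness_centrality(A)),
                   oracle_betweenness(A), tolerance = 1e-9)
      expect_equal(unname(closeness_centrality(A)),
                   oracle_closeness(A), tolerance = 1e-12)
      if (any(A != 0)) {
        ev <- suppressWarnings(eigenvector_centrality(A))
        expect_eigen_matches(A, ev$vector, ev$lambda)
      }
    }
  })
})

test_that("binary metrics agree with igraph on connected random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(78, {
    reps <- 0
    while (reps < 40) {
      n <- sample(4:8, 1)
      A <- random_graph(n, 0.5)
      if (length(unique(graph_components(A))) > 1) next
      reps <- reps + 1
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      expect_equal(unname(betweenness_centrality(A)),
                   unname(igraph::betweenness(g)), tolerance = 1e-9)
      expect_equal(unname(closeness_centrality(A)),
                   unname((n - 1) * igraph::closeness(g)),
                   tolerance = 1e-9)
    }
  })
})

test_that("weighted shortest-path metrics agree with igraph 1/|w| distances", {
  skip_if_not_installed("igraph")
  withr::with_seed(79, {
    reps <- 0
    while (reps < 40) {
      n <- sample(4:8, 1)
      A <- random_graph(n, 0.6, weighted = TRUE)
      if (length(unique(graph_components(A))) > 1) next
      reps <- reps + 1
      g <- igraph::graph_from_adjacency_matrix(
        abs(A), mode = "undirected", weighted = TRUE)
      wdist <- 1 / igraph::E(g)$weight
      expect_equal(unname(betweenness_centrality(A, mode = "weighted")),
                   unname(igraph::betweenness(g, weights = wdist)),
                   tolerance = 1e-8)
      expect_equal(unname(closeness_centrality(A, mode = "weighted")),
                   unname((n - 1) * igraph::closeness(g, weights = wdist)),
                   tolerance = 1e-8)
    }
  })
})

test_that("centrality is equivariant under node permutations", {
  withr::with_seed(80, {
    for (rep in 1:20) {
      n <- 7
      A <- random_graph(n, 0.5)
      if (all(A == 0)) next
      perm <- sample(n)
      Ap <- A[perm, perm]
      expect_equal(unname(degree_centrality(Ap)),
                   unname(degree_centrality(A))[perm])
      expect_equal(unname(betweenness_centrality(Ap)),
                   unname(betweenness_centrality(A))[perm],
                   tolerance = 1e-10)
      expect_equal(unname(closeness_centrality(Ap)),
                   unname(closeness_centrality(A))[perm],
                   tolerance = 1e-12)
      evA <- suppressWarnings(eigenvector_centrality(A))
      evP <- suppressWarnings(eigenvector_centrality(Ap))
      expect_equal(unname(evP$vector), unname(evA$vector)[perm],
                   tolerance = 1e-8)
    }
  })
})

test_that("adding an edge never decreases degree or endpoint closeness", {
  withr::with_seed(81, {
    for (rep in 1:20) {
      n <- 7
      A <- random_graph(n, 0.4)
      holes <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
      if (!nrow(holes)) next
      pick <- holes[sample(nrow(holes), 1), ]
      B <- A
      B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
      expect_true(all(degree_centrality(B) >= degree_centrality(A)))
      clA <- closeness_centrality(A)
      clB <- closeness_centrality(B)
      expect_gte(clB[pick[1]], clA[pick[1]] - 1e-12)
      expect_gte(clB[pick[2]], clA[pick[2]] - 1e-12)
    }
  })
})

test_that("betweenness splits ties fractionally", {
  # 4-cycle: two equally short paths between opposite corners, each middle
  # node carries half a pair for each of the two opposite pairs
  C4 <- matrix(0, 4, 4)
  C4[1, 2] <- C4[2, 3] <- C4[3, 4] <- C4[4, 1] <- 1
  C4 <- C4 + t(C4)
  expect_equal(unname(betweenness_centrality(C4)), rep(0.5, 4))
})

test_that("disconnected graphs follow the stated conventions", {
  # K3 plus an isolated node
  A <- matrix(0, 4, 4)
  A[1:3, 1:3] <- 1 - diag(3)
  expect_equal(unname(degree_centrality(A)), c(2L, 2L, 2L, 0L))
  expect_equal(unname(betweenness_centrality(A)), rep(0, 4))
  # Wasserman-Faust: C_i = (R/(N-1)) * (R/sum d): (2/3) * (2/2) = 2/3
  expect_equal(unname(closeness_centrality(A)), c(2 / 3, 2 / 3, 2 / 3, 0))
  expect_warning(ev <- eigenvector_centrality(A), "disconnected")
  expect_equal(ev$lambda, 2, tolerance = 1e-9)
  expect_equal(unname(ev$vector), c(1 / 3, 1 / 3, 1 / 3, 0),
               tolerance = 1e-9)
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "at least one edge")
})

test_that("the eigenvector equation E = A E / lambda holds on the profile", {
  co <- simulate_cohort(default_cohort_config(n_subjects = 120, seed = 82))
  corr <- pairwise_partial_correlations(compute_change_table(co),
                                        cohort_covariates(co))
  net <- threshold_network(corr, alpha = 0.05)
  prof <- suppressWarnings(centrality_profile(net))
  lambda <- attr(prof, "lambda")
  M <- (as_adjacency(net) != 0) * 1
  expect_equal(as.numeric(M %*% prof$eigenvector) / lambda,
               prof$eigenvector, tolerance = 1e-9)
  expect_equal(sum(prof$eigenvector), 1, tolerance = 1e-12)
  expect_true(all(prof$eigenvector >= 0))
  expect_true(all(prof$degree <= 37))
  expect_true(sum(prof$degree) %% 2 == 0)
})

test_that("consensus hubs: star center wins, clique symmetry ties", {
  s6 <- star_graph(6)
  prof <- centrality_profile(s6)
  hubs <- consensus_hubs(prof, k = 1)
  expect_equal(hubs$consensus, "V1")
  # two disjoint identical triangles: all metrics tie; top-3 is decided by
  # canonical order and reported as tied
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1 - diag(3)
  A[4:6, 4:6] <- 1 - diag(3)
  dimnames(A) <- list(paste0("V", 1:6), paste0("V", 1:6))
  prof2 <- suppressWarnings(centrality_profile(A))
  hubs2 <- consensus_hubs(prof2, k = 3)
  expect_true(all(hubs2$ties))
  expect_equal(hubs2$consensus, c("V1", "V2", "V3"))
  expect_error(consensus_hubs(prof2, k = 7), "between 1")
})

test_that("weighted and binary modes differ when weights are informative", {
  # triangle with a weak direct edge plus a pendant: in weighted mode the
  # 1-2-3 detour (length 2/0.9 = 2.22) beats the direct 1-3 edge
  # (length 1/0.1 = 10), so node 2 gains betweenness
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.9
  A[2, 3] <- A[3, 2] <- 0.9
  A[1, 3] <- A[3, 1] <- 0.1
  A[3, 4] <- A[4, 3] <- 0.8
  bin <- betweenness_centrality(A, "binary")
  wei <- betweenness_centrality(A, "weighted")
  expect_equal(unname(bin)[2], 0)
  expect_gt(unname(wei)[2], 0)
  d <- closeness_centrality(A, "weighted")
  expect_true(all(is.finite(d)))
})
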