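# Independent brute-force oracles used across the centrality and
# partial-correlation tests. They deliberately share no code with the
# package implementation: distances and geodesic counts come from powers of
# the binarized adjacency matrix, eigen-structure from eigen(), and partial
# correlations from the inverse-correlation-matrix identity.

random_graph <- function(n, p = 0.4, weighted = FALSE) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  edges <- stats::runif(sum(ut)) < p
  w <- if (weighted) stats::runif(sum(ut), 0.2, 1) *
    sample(c(-1, 1), sum(ut), TRUE) else 1
  A[ut] <- edges * w
  A <- A + t(A)
  dimnames(A) <- list(paste0("V", 1:n), paste0("V", 1:n))
  A
}

# shortest-path hop distances via matrix powers of the binarized adjacency
oracle_distances <- function(A) {
  B <- (A != 0) * 1
  n <- nrow(B)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(n - 1)) {
    P <- P %*% B
    new <- is.infinite(D) & P > 0
    D[new] <- k
  }
  diag(D) <- 0
  D
}

# geodesic counts: number of length-d(x,y) walks = (B^d)[x, y]
oracle_path_counts <- function(A) {
  B <- (A != 0) * 1
  n <- nrow(B)
  pow <- vector("list", n)
  pow[[1]] <- B
  for (k in seq_len(n - 1)[-1]) pow[[k]] <- pow[[k - 1]] %*% B
  list(D = oracle_distances(A), pow = pow)
}

oracle_betweenness <- function(A) {
  pc <- oracle_path_counts(A)
  D <- pc$D
  n <- nrow(D)
  g <- function(x, y) if (x == y) 1 else pc$pow[[D[x, y]]][x, y]
  b <- numeric(n)
  for (x in seq_len(n - 1)) for (y in (x + 1):n) {
    if (!is.finite(D[x, y])) next
    for (i in seq_len(n)) {
      if (i == x || i == y) next
      if (is.finite(D[x, i]) && is.finite(D[i, y]) &&
          D[x, i] + D[i, y] == D[x, y])
        b[i] <- b[i] + g(x, i) * g(i, y) / g(x, y)
    }
  }
  b
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    R <- sum(is.finite(di))
    if (R == 0) return(0)
    (R / (n - 1)) * (R / sum(di[is.finite(di)]))
  }, numeric(1))
}

# dense-eigensolver check of an (eigenvector, lambda) pair: lambda must be
# the top eigenvalue; if it is simple, the vectors must match after
# sign/scale alignment, otherwise the eigen-residual must vanish
expect_eigen_matches <- function(A, v, lambda, mode = "binary",
                                 tol = 1e-8) {
  M <- if (mode == "binary") (A != 0) * 1 else abs(A)
  ed <- eigen(M, symmetric = TRUE)
  expect_equal(lambda, ed$values[1], tolerance = tol)
  gap <- ed$values[1] - ed$values[min(2, length(ed$values))]
  if (gap > 1e-6) {
    ref <- ed$vectors[, 1]
    ref <- ref / sum(ref)
    expect_equal(unname(v), ref, tolerance = tol)
  }
  expect_lt(max(abs(M %*% v - lambda * v)), tol * max(1, lambda))
}

# partial correlation through the inverse-correlation-matrix identity
oracle_partial_cor <- function(x, y, Z) {
  S <- solve(stats::cor(cbind(x, y, Z)))
  -S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

# small helper: build a hippnet cohort directly from matrices
make_cohort <- function(vb, vf, mmse_b = NULL, mmse_f = NULL,
                        seed = 99) {
  n <- nrow(vb)
  ids <- hippnet::subfield_ids()
  dimnames(vb) <- dimnames(vf) <- list(sprintf("S%04d", 1:n), ids)
  withr::with_seed(seed, {
    subjects <- tibble::tibble(
      subject_id = rownames(vb),
      age = stats::rnorm(n, 75, 7),
      sex = stats::rbinom(n, 1, 0.4),
      education = sample(0:3, n, TRUE),
      apoe_e4_count = sample(0:2, n, TRUE),
      mmse_baseline = if (is.null(mmse_b))
        as.integer(sample(24:29, n, TRUE)) else as.integer(mmse_b),
      mmse_followup = if (is.null(mmse_f))
        as.integer(sample(20:28, n, TRUE)) else as.integer(mmse_f))
  })
  cohort <- list(subjects = subjects, volumes_baseline = vb,
                 volumes_followup = vf, config = NULL)
  class(cohort) <- "hippnet_cohort"
  hippnet::validate_cohort(cohort)
}
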