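#' Pairwise covariate-adjusted partial correlations between subfields
#'
#' Computes the 38 x 38 matrix of partial Pearson correlations between the
#' percentage volume changes of every subfield pair across subjects,
#' controlling for baseline age, sex, education band and APOE epsilon-4
#' allele count. All 38 change columns are residualised against the
#' intercept-augmented covariate design in a single QR pass, so the matrix
#' is exactly symmetric by construction. p-values use `df = n - k - 2`
#' (k = 4 covariates).
#'
#' @param changes A `hippnet_changes` tibble.
#' @param covariates Covariate tibble as from [cohort_covariates()].
#' @return A `hippnet_corr` object: list with `r` (symmetric, unit
#'   diagonal), `p` (symmetric, zero diagonal by convention), `n`, `df`,
#'   `labels` (canonical ids).
#' @export
pairwise_partial_correlations <- function(changes, covariates) {
  stopifnot(inherits(changes, "hippnet_changes"))
  if (!identical(covariates$subject_id, changes$subject_id))
    stop("covariates and changes refer to different subjects", call. = FALSE)
  Z <- as.matrix(covariates[, c("age", "sex", "education", "apoe_e4_count")])
  X <- change_matrix(changes)
  n <- nrow(X)
  qrz <- .covariate_qr(Z, n)
  if (n <= qrz$k + 2)
    stop("need n > k + 2 subjects for pairwise partial correlations",
         call. = FALSE)
  res <- .residualize(X, qrz$qr)
  sds <- apply(res, 2, stats::sd)
  bad <- sds <= 1e-10 * pmax(apply(X, 2, stats::sd), .Machine$double.xmin)
  if (any(bad))
    stop("degenerate input: zero-variance residuals for subfield(s) ",
         paste(colnames(X)[bad], collapse = ", "), call. = FALSE)
  r <- stats::cor(res)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  df <- n - qrz$k - 2L
  p <- .partial_cor_pvalue(r, df)
  diag(p) <- 0
  dimnames(p) <- dimnames(r)
  structure(list(r = r, p = p, n = n, df = df, labels = colnames(r)),
            class = "hippnet_corr")
}

#' @export
print.hippnet_corr <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat("<hippnet_corr>", length(x$labels), "nodes, n =", x$n,
      ", df =", x$df, "\n")
  cat(sprintf("  off-diagonal r: median %.3f, range [%.3f, %.3f]\n",
              stats::median(off), min(off), max(off)))
  invisible(x)
}

#' Significance-threshold a correlation matrix into a network
#'
#' Retains the partial correlation `r[i, j]` as the edge weight wherever
#' `p[i, j] < alpha` and sets every other entry (and the diagonal) to zero,
#' producing the weighted undirected structural covariance network. Edge
#' weights keep their sign; strength-based downstream computations use the
#' magnitude.
#'
#' @param corr A `hippnet_corr` from [pairwise_partial_correlations()], or
#'   a list with symmetric numeric matrices `r` and `p`.
#' @param alpha Per-edge significance level in (0, 1]; edges with p < alpha
#'   are retained (uncorrected by default, mirroring the per-edge p < 0.05
#'   rule).
#' @param fdr If `TRUE`, apply Benjamini-Hochberg correction to the
#'   upper-triangle p-values before thresholding.
#' @param positive_only If `TRUE`, drop negative-weight edges (by default
#'   they are retained).
#' @return A `hippnet_network`: list with `adjacency` (38 x 38 symmetric,
#'   zero diagonal, signed weights), `labels`, `alpha`, `fdr`,
#'   `positive_only`, `n_nodes`, `n_edges`.
#' @export
threshold_network <- function(corr, alpha = 0.05, fdr = FALSE,
                              positive_only = FALSE) {
  r <- corr$r
  p <- corr$p
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)) ||
      !isTRUE(all.equal(p, t(p), tolerance = 1e-12)))
    stop("correlation and p matrices must be symmetric", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  if (fdr) {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  keep <- p < alpha
  diag(keep) <- FALSE
  if (positive_only) keep <- keep & (r > 0)
  a <- ifelse(keep, r, 0)
  diag(a) <- 0
  new_network(a, labels = colnames(r), alpha = alpha, fdr = fdr,
              positive_only = positive_only)
}

new_network <- function(adjacency, labels = colnames(adjacency),
                        alpha = NA_real_, fdr = FALSE,
                        positive_only = FALSE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square", call. = FALSE)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(adjacency)))
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-12)))
    stop("adjacency must be symmetric", call. = FALSE)
  adjacency <- (adjacency + t(adjacency)) / 2
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels,
                 alpha = alpha, fdr = fdr, positive_only = positive_only,
                 n_nodes = nrow(adjacency),
                 n_edges = sum(adjacency[upper.tri(adjacency)] != 0)),
            class = "hippnet_network")
}

#' Coerce to an adjacency matrix
#'
#' @param x A `hippnet_network` or a symmetric numeric matrix.
#' @return The symmetric zero-diagonal weight matrix.
#' @export
as_adjacency <- function(x) {
  if (inherits(x, "hippnet_network")) return(x$adjacency)
  new_network(x)$adjacency
}

#' @export
print.hippnet_network <- function(x, ...) {
  cat("<hippnet_network>", x$n_nodes, "nodes,", x$n_edges, "edges")
  if (!is.na(x$alpha)) cat(sprintf(" (alpha = %g%s%s)", x$alpha,
                                   if (x$fdr) ", FDR" else "",
                                   if (x$positive_only) ", positive only" else ""))
  cat("\n")
  invisible(x)
}

#' Edge list of a thresholded network
#'
#' @param x A `hippnet_network`.
#' @param ... Unused.
#' @return A tibble with one row per retained edge: `node_i`, `node_j`
#'   (canonical ids, i before j in roster order), `weight` (signed partial
#'   correlation).
#' @export
tidy.hippnet_network <- function(x, ...) {
  a <- x$adjacency
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  tibble::tibble(node_i = x$labels[idx[, 1L]],
                 node_j = x$labels[idx[, 2L]],
                 weight = a[idx])
}

#' One-row network summary
#'
#' @param x A `hippnet_network`.
#' @param ... Unused.
#' @return A one-row tibble: node count, edge count, density, number of
#'   connected components, count of negative-weight edges, mean absolute
#'   weight.
#' @export
glance.hippnet_network <- function(x, ...) {
  a <- x$adjacency
  w <- a[upper.tri(a)]
  w <- w[w != 0]
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    density = x$n_edges / (x$n_nodes * (x$n_nodes - 1) / 2),
    n_components = length(unique(graph_components(a))),
    n_negative_edges = sum(w < 0),
    mean_abs_weight = if (length(w)) mean(abs(w)) else NA_real_)
}

#' Connected component labels of an adjacency matrix
#'
#' @param A Adjacency matrix or `hippnet_network` (any nonzero entry is an
#'   edge).
#' @return Integer vector of component labels (1-based) per node.
#' @export
graph_components <- function(A) {
  A <- as_adjacency(A)
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Convert a network to an igraph object
#'
#' @param x A `hippnet_network`.
#' @return An undirected `igraph` graph with a `weight` edge attribute
#'   (signed partial correlation). Requires the igraph package.
#' @export
as_igraph <- function(x) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  igraph::graph_from_adjacency_matrix(as_adjacency(x), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
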