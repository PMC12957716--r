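#' Degree centrality
#'
#' Binary degree: the number of (significance-retained) edges incident to
#' each node, regardless of stored edge weights. Bounded by N - 1 since the
#' network has no self-loops.
#'
#' @param A A `hippnet_network` or symmetric adjacency matrix (nonzero =
#'   edge).
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(A) {
  A <- as_adjacency(A)
  d <- rowSums(A != 0)
  storage.mode(d) <- "integer"
  d
}

# pairwise shortest-path structure: distances d, path counts sigma, and
# Brandes dependency-accumulated betweenness. Binary mode uses BFS;
# weighted mode uses Dijkstra on distances 1/|w| with a relative tolerance
# for equal-length path detection.
.shortest_paths <- function(A, mode = c("binary", "weighted"),
                            tol = 1e-12) {
  mode <- match.arg(mode)
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  len <- if (mode == "weighted") 1 / abs(A) else (A != 0) * 1
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  betw <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(Inf, n)
    dist[s] <- 0
    preds <- vector("list", n)
    order_settled <- integer(0)
    if (mode == "binary") {
      queue <- s
      while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        order_settled <- c(order_settled, v)
        for (w in nbrs[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            queue <- c(queue, w)
          }
          if (dist[w] == dist[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
    } else {
      settled <- logical(n)
      repeat {
        cand <- which(!settled & is.finite(dist))
        if (!length(cand)) break
        v <- cand[which.min(dist[cand])]
        settled[v] <- TRUE
        order_settled <- c(order_settled, v)
        for (w in nbrs[[v]]) {
          if (settled[w]) next
          nd <- dist[v] + len[v, w]
          eq_tol <- if (is.finite(dist[w])) tol * max(1, dist[w]) else 0
          if (nd < dist[w] - eq_tol) {
            dist[w] <- nd
            sigma[w] <- sigma[v]
            preds[[w]] <- v
          } else if (nd <= dist[w] + eq_tol) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
    }
    d[s, ] <- dist
    delta <- numeric(n)
    for (w in rev(order_settled)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) betw[w] <- betw[w] + delta[w]
    }
  }
  list(d = d, betweenness = betw / 2)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness (Brandes' dependency
#' accumulation): for each node i, the sum over unordered pairs x < y
#' (x, y != i) of the fraction of shortest x-y paths passing through i.
#' Equally short paths are counted fractionally; pairs with no connecting
#' path contribute zero. In weighted mode the edge length is `1/|weight|`,
#' so stronger co-atrophy means a shorter path.
#'
#' @param A A `hippnet_network` or symmetric adjacency matrix.
#' @param mode `"binary"` (default; hop-count shortest paths on the
#'   binarized graph) or `"weighted"`.
#' @return Named numeric vector of betweenness values.
#' @examples
#' path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
#' betweenness_centrality(path3)  # 0 1 0
#' @export
betweenness_centrality <- function(A, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  A <- as_adjacency(A)
  b <- .shortest_paths(A, mode)$betweenness
  names(b) <- rownames(A)
  b
}

#' Closeness centrality
#'
#' On a connected graph, `C_i = (N - 1) / sum_j l_ij` with `l_ij` the
#' shortest-path distance. On disconnected graphs the Wasserman-Faust
#' correction is used: `C_i = (R_i / (N - 1)) * (R_i / sum of distances to
#' reachable nodes)` with `R_i` the number of nodes reachable from i
#' (excluding i); isolated nodes score 0. In weighted mode distances are
#' sums of `1/|weight|` edge lengths.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector of closeness values.
#' @examples
#' star5 <- matrix(0, 5, 5); star5[1, 2:5] <- star5[2:5, 1] <- 1
#' closeness_centrality(star5)  # center 1, leaves 4/7
#' @export
closeness_centrality <- function(A, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  A <- as_adjacency(A)
  d <- .shortest_paths(A, mode)$d
  n <- nrow(A)
  cl <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    R <- sum(reach)
    if (R == 0) return(0)
    (R / (n - 1)) * (R / sum(di[reach]))
  }, numeric(1))
  names(cl) <- rownames(A)
  cl
}

#' Eigenvector centrality
#'
#' The principal eigenvector of the (binarized or absolute-weight)
#' adjacency matrix, L1-normalized so the components sum to 1, together
#' with the largest adjacency eigenvalue lambda; each component satisfies
#' `E_i = (1/lambda) * sum_j a_ij E_j`. Computed by power iteration with a
#' deterministic uniform start; the iteration runs on `A + I` (a unit
#' diagonal shift that preserves eigenvectors while preventing the
#' plus/minus eigenvalue oscillation of bipartite graphs), and lambda is
#' reported as the Rayleigh quotient on the unshifted matrix. On a
#' disconnected graph the result is dominated by the component with the
#' largest eigenvalue and a warning lists the components.
#'
#' @param A A `hippnet_network` or symmetric adjacency matrix with at least
#'   one edge.
#' @param mode `"binary"` (default) or `"weighted_abs"` (use `|a_ij|`, so
#'   the matrix stays non-negative and the principal eigenvector
#'   non-negative).
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   achieved residual.
#' @return A list: `vector` (named, non-negative, sums to 1) and `lambda`.
#' @examples
#' k4 <- 1 - diag(4)
#' eigenvector_centrality(k4)  # all 0.25, lambda 3
#' @export
eigenvector_centrality <- function(A, mode = c("binary", "weighted_abs"),
                                   tol = 1e-12, max_iter = 100000L) {
  mode <- match.arg(mode)
  A <- as_adjacency(A)
  n <- nrow(A)
  M <- if (mode == "binary") (A != 0) * 1 else abs(A)
  if (all(M == 0)) stop("eigenvector centrality needs at least one edge",
                        call. = FALSE)
  comp <- graph_components(M)
  if (length(unique(comp)) > 1L)
    warning("graph is disconnected (components: ",
            paste(table(comp), collapse = ", "),
            " nodes); eigenvector centrality is dominated by the ",
            "largest-eigenvalue component", call. = FALSE)
  S <- M + diag(n)  # spectral shift; same eigenvectors as M
  v <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(S %*% v)
    v_new <- v_new / sum(v_new)
    delta <- max(abs(v_new - v)) / max(v_new)
    v <- v_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(paste0("power iteration did not converge within %d ",
                        "iterations (residual %.3g)"), max_iter, delta),
         call. = FALSE)
  lambda <- as.numeric(v %*% (M %*% v)) / sum(v^2)
  names(v) <- rownames(A)
  list(vector = v, lambda = lambda)
}

#' Full centrality profile of a network
#'
#' Computes all four centrality metrics and the network eigen-pair in one
#' call. Degree is always binary; betweenness and closeness use `mode`;
#' eigenvector uses the binarized matrix in binary mode and `|weights|` in
#' weighted mode.
#'
#' @param network A `hippnet_network` or symmetric adjacency matrix.
#' @param mode `"binary"` (default) or `"weighted"` shortest-path /
#'   eigenvector mode.
#' @return A `hippnet_centrality` tibble, one row per node in canonical
#'   order: `id`, `label`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`; attributes `lambda` (largest adjacency eigenvalue) and
#'   `mode`.
#' @export
centrality_profile <- function(network, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  A <- as_adjacency(network)
  ev <- eigenvector_centrality(
    A, mode = if (mode == "binary") "binary" else "weighted_abs")
  labels <- rownames(A)
  pretty <- tryCatch(parse_subfield_label(labels)$label,
                     error = function(e) labels)
  out <- tibble::tibble(
    id = labels, label = pretty,
    degree = unname(degree_centrality(A)),
    betweenness = unname(betweenness_centrality(A, mode)),
    closeness = unname(closeness_centrality(A, mode)),
    eigenvector = unname(ev$vector))
  attr(out, "lambda") <- ev$lambda
  attr(out, "mode") <- mode
  class(out) <- c("hippnet_centrality", class(out))
  out
}

#' @export
glance.hippnet_centrality <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x), lambda = attr(x, "lambda"),
                 mode = attr(x, "mode"),
                 max_degree = max(x$degree),
                 max_betweenness = max(x$betweenness))
}

#' Consensus hub ranking across the four centrality metrics
#'
#' Ranks nodes per metric (descending value, ties broken by canonical
#' roster order) and intersects the four top-k sets: a consensus hub is a
#' node ranked in the top k for degree, betweenness, closeness and
#' eigenvector simultaneously. Boundary ties (k-th value equal to the
#' (k+1)-th) are reported per metric.
#'
#' @param profile A `hippnet_centrality` tibble.
#' @param k Top-rank cutoff (default 5); must be between 1 and the node
#'   count.
#' @return A `hippnet_hubs` list: `top` (named list of the four top-k id
#'   vectors), `consensus` (ids in every top-k set, in canonical order),
#'   `ranks` (tibble of per-metric ranks per node), `ties` (logical per
#'   metric: boundary tie at rank k), `k`, `mode`.
#' @examples
#' star5 <- matrix(0, 5, 5); star5[1, 2:5] <- star5[2:5, 1] <- 1
#' consensus_hubs(centrality_profile(star5), k = 1)$consensus
#' @export
consensus_hubs <- function(profile, k = 5) {
  stopifnot(inherits(profile, "hippnet_centrality"))
  n <- nrow(profile)
  if (!(k >= 1 && k <= n)) stop("k must be between 1 and the node count",
                                call. = FALSE)
  metrics <- c("degree", "betweenness", "closeness", "eigenvector")
  ranks <- tibble::tibble(id = profile$id, label = profile$label)
  top <- list()
  ties <- logical(length(metrics))
  names(ties) <- metrics
  for (m in metrics) {
    v <- profile[[m]]
    ord <- order(-v, seq_len(n))  # canonical order breaks ties
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    ranks[[paste0("rank_", m)]] <- rk
    top[[m]] <- profile$id[ord[seq_len(k)]]
    ties[m] <- k < n && v[ord[k]] == v[ord[k + 1L]]
  }
  consensus <- profile$id[profile$id %in% Reduce(intersect, top)]
  structure(list(top = top, consensus = consensus, ranks = ranks,
                 ties = ties, k = k, mode = attr(profile, "mode")),
            class = "hippnet_hubs")
}

#' @export
print.hippnet_hubs <- function(x, ...) {
  cat("<hippnet_hubs> top-", x$k, " consensus across 4 metrics (",
      x$mode, " mode)\n", sep = "")
  cat("  consensus:", if (length(x$consensus))
    paste(x$consensus, collapse = ", ") else "(none)", "\n")
  if (any(x$ties))
    cat("  boundary ties in:", paste(names(x$ties)[x$ties], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
tidy.hippnet_hubs <- function(x, ...) {
  dplyr::mutate(x$ranks, consensus = .data$id %in% x$consensus)
}
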