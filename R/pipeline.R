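#' Run the full subfield-network pipeline
#'
#' Chains every analysis stage in order: percentage-change computation,
#' per-subfield paired tests and the hemispheric asymmetry contrast, the
#' subfield-cognition partial-correlation associations, the pairwise
#' partial-correlation matrices, significance thresholding into the
#' structural covariance network, the four centrality metrics and the
#' consensus hub report. Every stage's output is written to `outdir`
#' together with a manifest recording the configuration, seed and package
#' version; an identical configuration and seed reproduce byte-identical
#' artifacts.
#'
#' @param cohort A `hippnet_cohort`, or `NULL` to simulate one from
#'   `config`.
#' @param outdir Output directory (created if missing).
#' @param config A `hippnet_config` used when `cohort` is `NULL`.
#' @param alpha Per-edge significance threshold for network edges
#'   (default 0.05).
#' @param mode Centrality shortest-path mode, `"binary"` (default) or
#'   `"weighted"`.
#' @param top_k Top-rank cutoff for consensus hubs (default 5).
#' @param fdr Apply Benjamini-Hochberg correction to edge p-values before
#'   thresholding (off by default).
#' @param verbose Log stage progress with [message()].
#' @return Invisibly, a list of all stage results (`cohort`, `changes`,
#'   `atrophy`, `asymmetry`, `associations`, `corr`, `network`,
#'   `centrality`, `hubs`, `files`).
#' @examples
#' \donttest{
#' out <- run_pipeline(outdir = tempfile(),
#'                     config = default_cohort_config(n_subjects = 40))
#' out$hubs$consensus
#' }
#' @export
run_pipeline <- function(cohort = NULL, outdir,
                         config = default_cohort_config(),
                         alpha = 0.05, mode = c("binary", "weighted"),
                         top_k = 5, fdr = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  if (!(top_k >= 1 && top_k <= 38)) stop("top_k must be in [1, 38]",
                                         call. = FALSE)
  say <- function(...) if (verbose) message("[hippnet] ", ...)
  simulated <- is.null(cohort)
  if (simulated) {
    say("simulating cohort: n = ", config$n_subjects,
        ", seed = ", config$seed)
    cohort <- simulate_cohort(config)
  } else {
    validate_cohort(cohort)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  covariates <- cohort_covariates(cohort)
  changes <- stage("changes", compute_change_table(cohort))
  say("changes: ", nrow(changes), " subjects x 38 subfields")
  atrophy <- stage("atrophy", subfield_atrophy_report(changes, cohort))
  asymmetry <- stage("asymmetry", hemispheric_asymmetry(changes))
  assoc <- stage("associations",
                 associate_cognition(changes, covariates, cohort = cohort))
  corr <- stage("correlations",
                pairwise_partial_correlations(changes, covariates))
  network <- stage("network",
                   threshold_network(corr, alpha = alpha, fdr = fdr))
  say("network: ", network$n_edges, " edges at alpha = ", alpha)
  if (length(unique(graph_components(network))) > 1L)
    say("note: network is disconnected")
  centrality <- stage("centrality",
                      suppressWarnings(centrality_profile(network, mode)))
  hubs <- stage("hubs", consensus_hubs(centrality, k = top_k))

  files <- c(changes = "changes.csv", atrophy = "atrophy_report.tsv",
             asymmetry = "asymmetry.tsv", associations = "associations.tsv",
             r = "network_r.csv", p = "network_p.csv",
             adjacency = "adjacency.csv", edges = "edge_list.tsv",
             centrality = "centrality.csv", hubs = "hubs.json",
             manifest = "manifest.json")
  paths <- stats::setNames(file.path(outdir, files), names(files))
  readr::write_csv(tibble::as_tibble(changes), paths["changes"])
  readr::write_tsv(atrophy, paths["atrophy"])
  readr::write_tsv(asymmetry, paths["asymmetry"])
  readr::write_tsv(assoc, paths["associations"])
  write_matrix_csv(corr$r, paths["r"])
  write_matrix_csv(corr$p, paths["p"])
  write_matrix_csv(network$adjacency, paths["adjacency"])
  readr::write_tsv(tidy(network), paths["edges"])
  readr::write_csv(tibble::as_tibble(centrality), paths["centrality"])
  jsonlite::write_json(
    list(top = hubs$top, consensus = hubs$consensus,
         ties = as.list(hubs$ties), k = hubs$k, mode = hubs$mode),
    paths["hubs"], auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "hippnet",
    version = as.character(utils::packageVersion("hippnet")),
    input = if (simulated) "simulated" else "external",
    config = if (simulated) .config_to_list(config) else NULL,
    n_subjects = nrow(cohort$subjects),
    alpha = alpha, fdr = fdr, mode = mode, top_k = top_k,
    n_edges = network$n_edges, files = as.list(files))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("wrote ", length(paths), " artifacts to ", outdir)
  invisible(list(cohort = cohort, changes = changes, atrophy = atrophy,
                 asymmetry = asymmetry, associations = assoc, corr = corr,
                 network = network, centrality = centrality, hubs = hubs,
                 files = paths))
}

.config_to_list <- function(config) {
  out <- unclass(config)
  out$factor_loadings <- list(
    rows = rownames(out$factor_loadings),
    columns = colnames(out$factor_loadings),
    values = apply(out$factor_loadings, 1, as.numeric, simplify = FALSE))
  out
}
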