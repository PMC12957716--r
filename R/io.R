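#' Write a cohort to a directory of CSV files
#'
#' Emits the four-file cohort layout shared by the readers: comma-separated,
#' UTF-8, `"."` decimals, header row mandatory, subfield columns in
#' canonical roster order, all files keyed by `subject_id`.
#'
#' @param cohort A `hippnet_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths (`volumes_baseline.csv`,
#'   `volumes_followup.csv`, `covariates.csv`, `cognition.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("volumes_baseline.csv", "volumes_followup.csv",
                            "covariates.csv", "cognition.csv"))
  vol_tbl <- function(m)
    dplyr::bind_cols(tibble::tibble(subject_id = rownames(m)),
                     tibble::as_tibble(m))
  readr::write_csv(vol_tbl(cohort$volumes_baseline), paths[1])
  readr::write_csv(vol_tbl(cohort$volumes_followup), paths[2])
  readr::write_csv(cohort_covariates(cohort), paths[3])
  readr::write_csv(dplyr::select(cohort$subjects, "subject_id",
                                 "mmse_baseline", "mmse_followup"), paths[4])
  invisible(paths)
}

#' Read a cohort from a directory of CSV files
#'
#' Reads the four-file layout written by [write_cohort()], validating as it
#' goes: the four files must share an identical `subject_id` set, the
#' volume files must contain exactly the canonical 38 subfield columns
#' (any order; they are reordered), all cells must be numeric, volumes
#' strictly positive, MMSE integer in `[0, 30]`. Unknown extra columns are
#' rejected. Errors name the offending file, subject and column.
#'
#' @param dir Directory containing `volumes_baseline.csv`,
#'   `volumes_followup.csv`, `covariates.csv` and `cognition.csv`.
#' @return A validated `hippnet_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  need <- c("volumes_baseline.csv", "volumes_followup.csv",
            "covariates.csv", "cognition.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing cohort file(s) in ", dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  read1 <- function(p) {
    x <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    if (!"subject_id" %in% names(x))
      stop(basename(p), ": no subject_id column", call. = FALSE)
    x$subject_id <- as.character(x$subject_id)
    if (anyNA(x)) {
      bad <- which(rowSums(is.na(x)) > 0)[1L]
      stop(basename(p), ": missing/non-numeric value at data row ", bad,
           " (subject ", x$subject_id[bad], ")", call. = FALSE)
    }
    x
  }
  vb_tbl <- read1(paths[1])
  vf_tbl <- read1(paths[2])
  cov_tbl <- read1(paths[3])
  cog_tbl <- read1(paths[4])

  key <- cov_tbl$subject_id
  for (i in seq_along(need)) {
    ids <- list(vb_tbl, vf_tbl, cov_tbl, cog_tbl)[[i]]$subject_id
    if (!setequal(ids, key) || anyDuplicated(ids))
      stop(need[i], ": subject_id set does not match covariates.csv",
           call. = FALSE)
  }
  roster_ids <- subfield_ids()
  vol_matrix <- function(tbl, fname) {
    cols <- setdiff(names(tbl), "subject_id")
    extra <- setdiff(cols, roster_ids)
    if (length(extra))
      stop(fname, ": unknown subfield column(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    miss <- setdiff(roster_ids, cols)
    if (length(miss))
      stop(fname, ": missing subfield column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    tbl <- tbl[match(key, tbl$subject_id), ]
    m <- as.matrix(tbl[, roster_ids])  # reorder to canonical roster
    if (!is.numeric(m))
      stop(fname, ": non-numeric volume cells", call. = FALSE)
    rownames(m) <- key
    m
  }
  vb <- vol_matrix(vb_tbl, need[1])
  vf <- vol_matrix(vf_tbl, need[2])
  cov_need <- c("subject_id", "age", "sex", "education", "apoe_e4_count")
  if (!setequal(names(cov_tbl), cov_need))
    stop("covariates.csv: expected exactly columns ",
         paste(cov_need, collapse = ", "), call. = FALSE)
  cog_need <- c("subject_id", "mmse_baseline", "mmse_followup")
  if (!setequal(names(cog_tbl), cog_need))
    stop("cognition.csv: expected exactly columns ",
         paste(cog_need, collapse = ", "), call. = FALSE)
  cog_tbl <- cog_tbl[match(key, cog_tbl$subject_id), ]
  subjects <- dplyr::bind_cols(
    cov_tbl[, cov_need],
    dplyr::mutate(cog_tbl[, c("mmse_baseline", "mmse_followup")],
                  dplyr::across(dplyr::everything(), as.integer)))
  subjects <- dplyr::mutate(
    subjects,
    sex = as.integer(.data$sex), education = as.integer(.data$education),
    apoe_e4_count = as.integer(.data$apoe_e4_count))
  new_cohort(subjects = subjects, volumes_baseline = vb,
             volumes_followup = vf)
}

#' Write a labeled square matrix as CSV
#'
#' @param m Numeric matrix with row/column names.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(m, path) {
  tbl <- dplyr::bind_cols(tibble::tibble(id = rownames(m)),
                          tibble::as_tibble(m))
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read a labeled square matrix written by [write_matrix_csv()]
#'
#' @param path CSV file with an `id` first column.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  m
}

#' Export a network in GraphML format
#'
#' Writes the thresholded network as GraphML with a `weight` edge
#' attribute, via igraph.
#'
#' @param network A `hippnet_network`.
#' @param path Output `.graphml` file.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
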