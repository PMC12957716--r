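#' Paired t-test of baseline vs follow-up measurements
#'
#' Two-sided paired t-test on `after - before` (via [stats::t.test()]):
#' t = mean(d) / (sd(d) / sqrt(n)) on n - 1 degrees of freedom, with sd the
#' usual n - 1 denominator sample SD. Degenerate inputs (n < 2, or
#' zero-variance differences, for which no finite t exists) are an error
#' rather than a silent p = 0.
#'
#' @param before,after Numeric vectors of equal length (n >= 2).
#' @return A one-row tibble: `mean_diff`, `t_stat`, `p_value`, `n`, `df`.
#' @examples
#' paired_t_test(c(5, 6, 7), c(6, 8, 7))  # t = sqrt(3)
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have equal length", call. = FALSE)
  n <- length(before)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test is degenerate",
         call. = FALSE)
  ht <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(mean_diff = unname(ht$estimate),
                 t_stat = unname(ht$statistic),
                 p_value = ht$p.value, n = n, df = n - 1L)
}

#' Per-subfield longitudinal atrophy report
#'
#' For each of the 38 subfields, tests raw follow-up against baseline
#' volumes with a paired t-test across subjects, and reports the mean of the
#' per-subject percentage changes (the per-subject ratio convention, matching
#' the per-subject change formula; not the ratio of mean volumes).
#'
#' @param changes A `hippnet_changes` tibble from [compute_change_table()].
#' @param cohort The `hippnet_cohort` the changes were computed from.
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted `p_fdr`
#'   column. Off by default: per-subfield p-values are reported uncorrected.
#' @return A tibble with one row per subfield, in canonical roster order:
#'   `id`, `label`, `mean_baseline`, `mean_followup`, `mean_change_pct`,
#'   `t_stat`, `p_value`, `n`, `df` (and `p_fdr` when requested). Sortable
#'   by `mean_change_pct`.
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_subjects = 40))
#' rep <- subfield_atrophy_report(compute_change_table(cohort), cohort)
#' dplyr::arrange(rep, mean_change_pct)
#' @export
subfield_atrophy_report <- function(changes, cohort, fdr = FALSE) {
  stopifnot(inherits(changes, "hippnet_changes"))
  validate_cohort(cohort)
  if (!identical(changes$subject_id, cohort$subjects$subject_id))
    stop("changes and cohort refer to different subjects", call. = FALSE)
  roster <- subfield_roster()
  ch <- change_matrix(changes)
  out <- purrr::map_dfr(roster$id, function(j) {
    tt <- paired_t_test(cohort$volumes_baseline[, j],
                        cohort$volumes_followup[, j])
    tibble::tibble(
      id = j,
      mean_baseline = mean(cohort$volumes_baseline[, j]),
      mean_followup = mean(cohort$volumes_followup[, j]),
      mean_change_pct = mean(ch[, j]),
      t_stat = tt$t_stat, p_value = tt$p_value, n = tt$n, df = tt$df)
  })
  out <- dplyr::left_join(out, dplyr::select(roster, "id", "label"),
                          by = "id") |>
    dplyr::relocate("label", .after = "id")
  if (fdr) out$p_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Left vs right hemispheric asymmetry of atrophy
#'
#' Per subject, averages the percentage volume change over the 19 left and
#' the 19 right subfields (unweighted by default) and paired-t-tests the
#' left against the right per-subject means. A negative `mean_diff` means
#' the left hemisphere lost proportionally more volume.
#'
#' @param changes A `hippnet_changes` tibble.
#' @param weights Optional named non-negative weights over the 38 subfield
#'   ids (e.g. baseline volumes) for volume-weighted hemisphere means;
#'   `NULL` (default) gives the unweighted mean.
#' @return A one-row tibble: `left_mean_pct`, `right_mean_pct`, `mean_diff`
#'   (left minus right), `t_stat`, `p_value`, `n`, `df`.
#' @export
hemispheric_asymmetry <- function(changes, weights = NULL) {
  stopifnot(inherits(changes, "hippnet_changes"))
  ch <- change_matrix(changes)
  hemi_mean <- function(h) {
    ids <- subfield_ids(h)
    if (is.null(weights)) return(rowMeans(ch[, ids, drop = FALSE]))
    w <- weights[ids]
    if (anyNA(w) || any(w < 0)) stop("weights must cover all subfield ids ",
                                     "and be non-negative", call. = FALSE)
    as.numeric(ch[, ids, drop = FALSE] %*% (w / sum(w)))
  }
  left <- hemi_mean("L")
  right <- hemi_mean("R")
  tt <- paired_t_test(right, left)  # d = left - right
  tibble::tibble(left_mean_pct = mean(left), right_mean_pct = mean(right),
                 mean_diff = tt$mean_diff, t_stat = tt$t_stat,
                 p_value = tt$p_value, n = tt$n, df = tt$df)
}

#' Aggregate-region change scores from summed volumes
#'
#' Aggregate regions (whole hippocampus, whole head, whole body, per
#' hemisphere) are computed by summing constituent subfield volumes before
#' the change computation; they are reporting conveniences and never enter
#' the covariance network.
#'
#' @param cohort A `hippnet_cohort`.
#' @return A tibble: `subject_id`, then one percentage-change column per
#'   aggregate (`Whole_hippocampus_L/R`, `Whole_head_L/R`, `Whole_body_L/R`).
#' @export
aggregate_changes <- function(cohort) {
  validate_cohort(cohort)
  roster <- subfield_roster()
  groups <- list(
    Whole_hippocampus_L = roster$id[roster$hemisphere == "L"],
    Whole_hippocampus_R = roster$id[roster$hemisphere == "R"],
    Whole_head_L = roster$id[roster$hemisphere == "L" & roster$part == "head"],
    Whole_head_R = roster$id[roster$hemisphere == "R" & roster$part == "head"],
    Whole_body_L = roster$id[roster$hemisphere == "L" & roster$part == "body"],
    Whole_body_R = roster$id[roster$hemisphere == "R" & roster$part == "body"])
  cols <- purrr::imap(groups, function(ids, nm) {
    b <- rowSums(cohort$volumes_baseline[, ids, drop = FALSE])
    f <- rowSums(cohort$volumes_followup[, ids, drop = FALSE])
    unname(percent_change(b, f, what = paste("aggregate", nm)))
  })
  dplyr::bind_cols(tibble::tibble(subject_id = cohort$subjects$subject_id),
                   tibble::as_tibble(cols))
}
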