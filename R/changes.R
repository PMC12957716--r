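#' Percentage change from baseline
#'
#' The elementary change score used for both subfield volumes and MMSE:
#' `100 * (followup - baseline) / baseline`. Negative values indicate loss
#' (atrophy, cognitive decline).
#'
#' @param baseline Numeric vector of strictly positive baseline values.
#' @param followup Numeric vector of follow-up values (recycled against
#'   `baseline` by the usual rules; lengths must match or be 1).
#' @param what Label used in the error message when a baseline is
#'   non-positive.
#' @return Numeric vector of percentage changes.
#' @examples
#' percent_change(4000, 3600)  # -10
#' percent_change(30, 33)      # +10
#' @export
percent_change <- function(baseline, followup, what = "baseline") {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    i <- which(!is.finite(baseline) | baseline <= 0)[1L]
    nm <- names(baseline)[i]
    stop(sprintf("non-positive %s value at position %d%s", what, i,
                 if (is.null(nm)) "" else paste0(" (", nm, ")")),
         call. = FALSE)
  }
  100 * (followup - baseline) / baseline
}

#' Compute the per-subject change table
#'
#' Applies [percent_change()] element-wise to the 38 subfield volume columns
#' and to the MMSE scores, producing the package's central data object: one
#' row per subject with the percentage volume change of every subfield and
#' the percentage cognitive decline.
#'
#' @param cohort A `hippnet_cohort`.
#' @return A `hippnet_changes` tibble: `subject_id`,
#'   `cognitive_decline_pct`, then one column per canonical subfield id
#'   (percent volume change), rows in cohort subject order.
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_subjects = 10))
#' changes <- compute_change_table(cohort)
#' changes[, 1:4]
#' @export
compute_change_table <- function(cohort) {
  validate_cohort(cohort)
  vb <- cohort$volumes_baseline
  vf <- cohort$volumes_followup
  ch <- matrix(NA_real_, nrow(vb), ncol(vb), dimnames = dimnames(vb))
  for (j in colnames(vb))
    ch[, j] <- percent_change(vb[, j], vf[, j], what = paste("volume", j))
  s <- cohort$subjects
  decline <- percent_change(as.numeric(s$mmse_baseline),
                            as.numeric(s$mmse_followup), what = "MMSE")
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = s$subject_id,
                   cognitive_decline_pct = decline),
    tibble::as_tibble(ch))
  class(out) <- c("hippnet_changes", class(out))
  out
}

#' Extract the subjects x 38 change matrix
#'
#' @param changes A `hippnet_changes` tibble.
#' @return Numeric matrix of percentage volume changes, rows named by
#'   subject, columns in canonical roster order.
#' @export
change_matrix <- function(changes) {
  stopifnot(inherits(changes, "hippnet_changes"))
  ids <- subfield_ids()
  m <- as.matrix(changes[, ids])
  rownames(m) <- changes$subject_id
  m
}

#' Pivot a change table to long format
#'
#' @param x A `hippnet_changes` tibble.
#' @param ... Unused.
#' @return A tibble with one row per subject x subfield: `subject_id`,
#'   `id`, `label`, `hemisphere`, `volume_change_pct`,
#'   `cognitive_decline_pct`.
#' @export
tidy.hippnet_changes <- function(x, ...) {
  roster <- subfield_roster()
  tidyr::pivot_longer(tibble::as_tibble(x), cols = dplyr::all_of(roster$id),
                      names_to = "id", values_to = "volume_change_pct") |>
    dplyr::left_join(dplyr::select(roster, "id", "label", "hemisphere"),
                     by = "id") |>
    dplyr::select("subject_id", "id", "label", "hemisphere",
                  "volume_change_pct", "cognitive_decline_pct")
}
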