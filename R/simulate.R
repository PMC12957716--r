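#' Simulate a longitudinal subfield cohort
#'
#' Draws a synthetic cohort from the latent-factor co-atrophy model described
#' in [cohort_config()]. All randomness is consumed from a generator seeded
#' once with `config$seed` (the caller's RNG state is untouched), so the same
#' configuration always yields a bit-identical cohort.
#'
#' Baseline volumes are log-normal (mean matching `baseline_volume_means`),
#' guaranteeing positivity; follow-up volumes are
#' `baseline * (1 + change/100)`. MMSE scores are integers clipped to
#' `[0, 30]`; the latent percentage decline (mean `mmse_decline_mean`, SD
#' `mmse_decline_sd`, first-factor weight `cognition_coupling`) is applied to
#' the baseline score before rounding, so observed decline percentages carry
#' a small additional rounding component.
#'
#' @param config A `hippnet_config`, e.g. [default_cohort_config()].
#' @return A `hippnet_cohort`: a list with
#'   \item{subjects}{tibble of per-subject covariates and MMSE scores:
#'     `subject_id`, `age` (years), `sex` (1 = female), `education`
#'     (ordinal band 0-3), `apoe_e4_count` (0/1/2), `mmse_baseline`,
#'     `mmse_followup`.}
#'   \item{volumes_baseline, volumes_followup}{numeric matrices, subjects x
#'     38, columns in canonical roster order, rows named by `subject_id`.}
#'   \item{config}{the generating configuration.}
#'   \item{latent_decline_pct}{the continuous percentage MMSE decline before
#'     rounding/clipping of the follow-up score (simulated cohorts only;
#'     diagnostic for generator validation).}
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_subjects = 20))
#' cohort
#' @export
simulate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, .draw_cohort(config))
}

.draw_cohort <- function(config) {
  n <- config$n_subjects
  ids <- subfield_ids()
  subject_id <- sprintf("S%04d", seq_len(n))

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$prop_female)
  apoe <- sample(c(2L, 1L, 0L), n, replace = TRUE, prob = config$apoe_probs)
  education <- sample(0:3, n, replace = TRUE, prob = config$education_probs)
  mmse_baseline <- pmin(pmax(round(stats::rnorm(
    n, config$mmse_baseline_mean, config$mmse_baseline_sd)), 0L), 30L)

  L <- config$factor_loadings
  k <- ncol(L)
  f <- matrix(stats::rnorm(n * k), n, k)
  eps <- matrix(stats::rnorm(n * 38L, 0, config$noise_sd), n, 38L)
  change <- matrix(config$atrophy_means, n, 38L, byrow = TRUE) +
    f %*% t(L) + eps

  mlog <- log(config$baseline_volume_means) - config$baseline_volume_sdlog^2 / 2
  vb <- exp(matrix(mlog, n, 38L, byrow = TRUE) +
              matrix(stats::rnorm(n * 38L, 0, config$baseline_volume_sdlog),
                     n, 38L))
  vf <- vb * (1 + change / 100)

  resid_sd <- sqrt(config$mmse_decline_sd^2 - config$cognition_coupling^2)
  decline <- config$mmse_decline_mean + stats::rnorm(n, 0, resid_sd)
  if (config$cognition_coupling != 0)
    decline <- decline + config$cognition_coupling * f[, 1L]
  mmse_followup <- as.integer(
    pmin(pmax(round(mmse_baseline * (1 + decline / 100)), 0L), 30L))

  dimnames(vb) <- dimnames(vf) <- list(subject_id, ids)
  cohort <- new_cohort(
    subjects = tibble::tibble(
      subject_id = subject_id, age = age, sex = sex,
      education = as.integer(education), apoe_e4_count = apoe,
      mmse_baseline = as.integer(mmse_baseline),
      mmse_followup = mmse_followup),
    volumes_baseline = vb, volumes_followup = vf, config = config)
  # latent (pre-rounding, pre-clipping) decline: the quantity the config
  # moments parametrise; observed integer MMSE adds rounding noise and
  # ceiling truncation on top
  cohort$latent_decline_pct <- decline
  cohort
}

new_cohort <- function(subjects, volumes_baseline, volumes_followup,
                       config = NULL) {
  cohort <- structure(
    list(subjects = subjects, volumes_baseline = volumes_baseline,
         volumes_followup = volumes_followup, config = config),
    class = "hippnet_cohort")
  validate_cohort(cohort)
}

#' Validate a longitudinal cohort
#'
#' Enforces the cohort contract every downstream stage relies on: no missing
#' values, unique subject ids shared (in order) by all components, strictly
#' positive volumes, the canonical 38-column roster order, and MMSE scores
#' in `[0, 30]`.
#'
#' @param cohort A `hippnet_cohort`.
#' @return The cohort, unchanged.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "hippnet_cohort"))
  s <- cohort$subjects
  vb <- cohort$volumes_baseline
  vf <- cohort$volumes_followup
  if (anyDuplicated(s$subject_id))
    stop("duplicate subject_id in cohort", call. = FALSE)
  if (!identical(rownames(vb), s$subject_id) ||
      !identical(rownames(vf), s$subject_id))
    stop("volume matrix rows must match subjects$subject_id order",
         call. = FALSE)
  ids <- subfield_ids()
  if (!identical(colnames(vb), ids) || !identical(colnames(vf), ids))
    stop("volume matrix columns must be the canonical 38 subfield ids ",
         "in roster order", call. = FALSE)
  if (anyNA(s) || anyNA(vb) || anyNA(vf))
    stop("cohort contains missing values", call. = FALSE)
  for (nm in c("volumes_baseline", "volumes_followup")) {
    v <- cohort[[nm]]
    if (any(v <= 0)) {
      bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-positive volume in %s: subject %s, subfield %s",
                   nm, rownames(v)[bad[1L]], colnames(v)[bad[2L]]),
           call. = FALSE)
    }
  }
  if (any(s$mmse_baseline < 0 | s$mmse_baseline > 30 |
          s$mmse_followup < 0 | s$mmse_followup > 30))
    stop("MMSE scores must lie in [0, 30]", call. = FALSE)
  cohort
}

#' Extract the covariate table of a cohort
#'
#' The four adjustment covariates used throughout the association and
#' network stages: baseline age, sex, education band and APOE epsilon-4
#' allele count.
#'
#' @param cohort A `hippnet_cohort`.
#' @return A tibble with `subject_id`, `age`, `sex`, `education`,
#'   `apoe_e4_count`.
#' @export
cohort_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "hippnet_cohort"))
  dplyr::select(cohort$subjects, "subject_id", "age", "sex",
                "education", "apoe_e4_count")
}

#' @export
print.hippnet_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<hippnet_cohort>", nrow(s), "subjects x 38 subfields\n")
  cat(sprintf("  age %.2f (%.2f) y; %.1f%% female; MMSE %.2f -> %.2f\n",
              mean(s$age), stats::sd(s$age), 100 * mean(s$sex),
              mean(s$mmse_baseline), mean(s$mmse_followup)))
  invisible(x)
}

#' @rdname glance.hippnet_cohort
#' @export
glance.hippnet_cohort <- function(x, ...) {
  s <- x$subjects
  decline <- 100 * (s$mmse_followup - s$mmse_baseline) / s$mmse_baseline
  tibble::tibble(
    n_subjects = nrow(s),
    age_mean = mean(s$age), age_sd = stats::sd(s$age),
    prop_female = mean(s$sex),
    mmse_baseline_mean = mean(s$mmse_baseline),
    mmse_decline_mean_pct = mean(decline),
    mmse_decline_sd_pct = stats::sd(decline))
}

#' One-row cohort summary
#'
#' @param x A `hippnet_cohort`.
#' @param ... Unused.
#' @return A one-row tibble of cohort-level summary statistics.
#' @name glance.hippnet_cohort
NULL
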