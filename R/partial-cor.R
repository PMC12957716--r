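#' Covariate-adjusted partial Pearson correlation
#'
#' Partial correlation of `x` and `y` given covariates `Z`: both variables
#' are residualised against `[1, Z]` by least squares (QR factorisation)
#' and the Pearson correlation of the residuals is returned. The two-sided
#' p-value comes from `t = r * sqrt(df / (1 - r^2))` on `df = n - k - 2`
#' degrees of freedom, with k the number of covariate columns. With no
#' covariates (`Z = NULL` or zero columns) this reduces to the ordinary
#' Pearson correlation with `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length n.
#' @param Z Optional numeric covariate matrix or data frame (n rows, k
#'   columns); an intercept is always included internally. Must be full
#'   column rank together with the intercept, and n > k + 2.
#' @return A one-row tibble: `r`, `p_value`, `n`, `df`.
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(200), 50)
#' x <- rnorm(50) + Z[, 1]
#' y <- rnorm(50) + Z[, 1]
#' partial_correlation(x, y, Z)
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  qrz <- .covariate_qr(Z, n)
  k <- qrz$k
  if (n <= k + 2)
    stop("need n > k + 2 observations for a partial correlation",
         call. = FALSE)
  res <- .residualize(cbind(x, y), qrz$qr)
  r <- .residual_correlation(res[, 1L], res[, 2L], "x and y",
                             scale_x = stats::sd(x), scale_y = stats::sd(y))
  df <- n - k - 2L
  tibble::tibble(r = r, p_value = .partial_cor_pvalue(r, df),
                 n = n, df = df)
}

# QR of the intercept-augmented design; errors on rank deficiency
.covariate_qr <- function(Z, n) {
  if (is.null(Z)) {
    design <- matrix(1, n, 1)
    k <- 0L
  } else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    if (nrow(Z) != n) stop("Z must have one row per observation",
                           call. = FALSE)
    design <- cbind(`(Intercept)` = 1, Z)
    k <- ncol(Z)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("covariate matrix is rank deficient with the intercept",
         call. = FALSE)
  list(qr = qrd, k = k)
}

.residualize <- function(M, qrd) qr.resid(qrd, M)

# residual variance below ~1e-10 of the input scale means the variable is
# (numerically) an exact linear function of the covariates
.residual_correlation <- function(rx, ry, what, scale_x = 1, scale_y = 1) {
  if (stats::sd(rx) <= 1e-10 * max(scale_x, .Machine$double.xmin) ||
      stats::sd(ry) <= 1e-10 * max(scale_y, .Machine$double.xmin))
    stop("degenerate input: zero-variance residuals for ", what,
         call. = FALSE)
  stats::cor(rx, ry)
}

.partial_cor_pvalue <- function(r, df) {
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

#' Subfield atrophy vs cognitive decline associations
#'
#' For every subfield (and optionally the summed-volume aggregates),
#' computes the partial Pearson correlation between its percentage volume
#' change and the percentage MMSE decline, adjusting for baseline age, sex,
#' education band and APOE epsilon-4 allele count. Significance is flagged
#' at the usual star levels (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param changes A `hippnet_changes` tibble.
#' @param covariates Covariate tibble as from [cohort_covariates()]
#'   (`subject_id`, `age`, `sex`, `education`, `apoe_e4_count`), matching
#'   the subjects of `changes`.
#' @param cohort Optional `hippnet_cohort`; when supplied, aggregate-region
#'   rows (summed volumes, see [aggregate_changes()]) are appended.
#' @return A tibble, one row per subfield (aggregates last when requested):
#'   `id`, `label`, `r`, `p_value`, `n`, `df`, `stars`. Sortable by `r`.
#' @export
associate_cognition <- function(changes, covariates, cohort = NULL) {
  stopifnot(inherits(changes, "hippnet_changes"))
  if (!identical(covariates$subject_id, changes$subject_id))
    stop("covariates and changes refer to different subjects", call. = FALSE)
  Z <- as.matrix(covariates[, c("age", "sex", "education", "apoe_e4_count")])
  y <- changes$cognitive_decline_pct
  ch <- change_matrix(changes)
  roster <- subfield_roster()
  targets <- tibble::tibble(id = roster$id, label = roster$label)
  X <- ch
  if (!is.null(cohort)) {
    agg <- aggregate_changes(cohort)
    if (!identical(agg$subject_id, changes$subject_id))
      stop("cohort and changes refer to different subjects", call. = FALSE)
    agg_m <- as.matrix(agg[, -1])
    targets <- dplyr::bind_rows(
      targets,
      tibble::tibble(id = colnames(agg_m),
                     label = gsub("_", " ", colnames(agg_m))))
    X <- cbind(X, agg_m)
  }
  n <- length(y)
  qrz <- .covariate_qr(Z, n)
  res <- .residualize(cbind(y, X), qrz$qr)
  ry <- res[, 1L]
  df <- n - qrz$k - 2L
  sy <- stats::sd(y)
  out <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    r <- .residual_correlation(res[, j + 1L], ry,
                               paste0(colnames(X)[j], " vs cognition"),
                               scale_x = stats::sd(X[, j]), scale_y = sy)
    tibble::tibble(r = r, p_value = .partial_cor_pvalue(r, df))
  })
  dplyr::bind_cols(targets, out) |>
    dplyr::mutate(n = n, df = df, stars = p_stars(.data$p_value))
}

#' Significance stars
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}
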