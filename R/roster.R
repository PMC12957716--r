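#' Canonical hippocampal subfield roster
#'
#' The analysis operates on the 38 hippocampal subfield regions produced by
#' FreeSurfer's probabilistic subfield segmentation: seven structures split
#' into head and body segments (CA1, CA3, CA4, dentate gyrus, molecular
#' layer, subiculum, presubiculum) plus five unsplit structures
#' (parasubiculum, fimbria, HATA, hippocampal tail, hippocampal fissure),
#' each in both hemispheres — 19 regions per hemisphere.
#'
#' The roster order is canonical: every volume matrix, change table,
#' correlation matrix and centrality report in the package uses this order,
#' and readers reorder input columns to it.
#'
#' @return A tibble with 38 rows and columns `id` (machine-safe unique key,
#'   e.g. `"CA1_body_L"`), `label` (display form, e.g. `"CA1 body L"`),
#'   `structure`, `part` (`"head"`, `"body"` or `"whole"`) and
#'   `hemisphere` (`"L"` or `"R"`).
#' @examples
#' subfield_roster()
#' @export
subfield_roster <- function() {
  spec <- .subfield_structures
  rows <- purrr::pmap_dfr(spec, function(structure, display, split) {
    parts <- if (split) c("body", "head") else "whole"
    tidyr::expand_grid(part = parts, hemisphere = c("L", "R")) |>
      dplyr::mutate(structure = structure, display = display)
  })
  rows |>
    dplyr::mutate(
      label = ifelse(.data$part == "whole",
                     paste(.data$display, .data$hemisphere),
                     paste(.data$display, .data$part, .data$hemisphere)),
      id = gsub(" ", "_", .data$label)
    ) |>
    dplyr::select("id", "label", "structure", "part", "hemisphere")
}

# structure roster in canonical (display-alphabetical) order, as in the
# standard subfield table layout
.subfield_structures <- tibble::tribble(
  ~structure,            ~display,              ~split,
  "CA1",                 "CA1",                 TRUE,
  "CA3",                 "CA3",                 TRUE,
  "CA4",                 "CA4",                 TRUE,
  "dentate_gyrus",       "Dentate gyrus",       TRUE,
  "HATA",                "HATA",                FALSE,
  "hippocampal_tail",    "Hippocampal tail",    FALSE,
  "fimbria",             "Fimbria",             FALSE,
  "hippocampal_fissure", "Hippocampal fissure", FALSE,
  "molecular_layer",     "Molecular layer",     TRUE,
  "parasubiculum",       "Parasubiculum",       FALSE,
  "presubiculum",        "Presubiculum",        TRUE,
  "subiculum",           "Subiculum",           TRUE
)

#' Canonical subfield identifiers
#'
#' @param hemisphere Optionally restrict to one hemisphere (`"L"` or `"R"`).
#' @return Character vector of subfield `id`s in canonical roster order
#'   (length 38, or 19 when restricted).
#' @export
subfield_ids <- function(hemisphere = NULL) {
  r <- subfield_roster()
  if (!is.null(hemisphere)) {
    hemisphere <- match.arg(hemisphere, c("L", "R"))
    r <- dplyr::filter(r, .data$hemisphere == !!hemisphere)
  }
  r$id
}

#' Parse subfield labels or identifiers
#'
#' Accepts either the display form (`"CA1 body L"`) or the id form
#' (`"CA1_body_L"`); parsing is exact (unknown labels are an error) and
#' round-trips through [subfield_roster()].
#'
#' @param x Character vector of labels or ids.
#' @return A tibble with one row per input, columns as [subfield_roster()].
#' @examples
#' parse_subfield_label(c("CA1 body L", "Parasubiculum_R"))
#' @export
parse_subfield_label <- function(x) {
  stopifnot(is.character(x))
  r <- subfield_roster()
  idx <- match(x, r$id)
  idx[is.na(idx)] <- match(x[is.na(idx)], r$label)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown subfield label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r[idx, ]
}
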