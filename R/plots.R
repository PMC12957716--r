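#' Heatmap of the partial-correlation matrices
#'
#' @param object A `hippnet_corr`.
#' @param which `"r"` (default) or `"p"`.
#' @param ... Unused.
#' @return A ggplot object: node x node tile heatmap in canonical roster
#'   order (diverging fill for r, sequential for p).
#' @export
autoplot.hippnet_corr <- function(object, which = c("r", "p"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- tibble::as_tibble(m) |>
    dplyr::mutate(row = factor(rownames(m), levels = rownames(m))) |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "value") |>
    dplyr::mutate(col = factor(.data$col, levels = colnames(m)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (which == "r") "partial r" else "p-value") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = .5))
  if (which == "r")
    p + ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
      ggplot2::scale_y_discrete(limits = rev)
  else
    p + ggplot2::scale_fill_gradient(low = "#132B43", high = "#FFF7BC") +
      ggplot2::scale_y_discrete(limits = rev)
}

#' Bar chart of centrality values per metric
#'
#' @param object A `hippnet_centrality` tibble.
#' @param ... Unused.
#' @return A ggplot object: nodes on the y axis, one facet per metric
#'   (free x scales), bars colored by hemisphere.
#' @export
autoplot.hippnet_centrality <- function(object, ...) {
  roster <- subfield_roster()
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("degree", "betweenness", "closeness",
                          "eigenvector"),
                        names_to = "metric", values_to = "value") |>
    dplyr::left_join(dplyr::select(roster, "id", "hemisphere"), by = "id") |>
    dplyr::mutate(label = factor(.data$label, levels = rev(roster$label)))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$label,
                                   fill = .data$hemisphere)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "hemisphere") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Forest-style plot of per-subfield mean atrophy
#'
#' @param report Atrophy report tibble from [subfield_atrophy_report()].
#' @return A ggplot object: subfields ordered by mean percentage change,
#'   point per subfield, significance stars appended to labels.
#' @export
plot_atrophy <- function(report) {
  df <- dplyr::mutate(report,
                      shown = paste0(.data$label, " ",
                                     p_stars(.data$p_value)),
                      hemisphere = sub("^.* ", "", .data$label))
  ggplot2::ggplot(df, ggplot2::aes(
    .data$mean_change_pct,
    stats::reorder(.data$shown, .data$mean_change_pct),
    color = .data$hemisphere)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean volume change (%)", y = NULL,
                  color = "hemisphere") +
    ggplot2::theme_minimal(base_size = 8)
}
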