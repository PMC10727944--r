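# ggplot2 views of feature tables and search results.

#' Pseudo-chromatogram of a feature table or search result
#'
#' Intensity against retention time, one vertical segment per feature. For a
#' search result, segments are coloured by match provenance (direct,
#' satellite-merged, unidentified).
#'
#' @param x A feature tibble (`rt`, `intensity` columns) or a
#'   `pg_search_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(x, ...) {
  if (inherits(x, "pg_search_result")) {
    d <- x$matches |>
      dplyr::filter(.data$primary | .data$provenance != "direct") |>
      dplyr::distinct(.data$feature_id, .keep_all = TRUE)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$rt, xend = .data$rt,
                                    y = 0, yend = .data$intensity,
                                    colour = .data$provenance)) +
      ggplot2::geom_segment(linewidth = 0.6) +
      ggplot2::labs(x = "Retention time (min)", y = "Intensity",
                    colour = "Provenance") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(x, ggplot2::aes(x = .data$rt, xend = .data$rt,
                                    y = 0, yend = .data$intensity)) +
      ggplot2::geom_segment(linewidth = 0.6) +
      ggplot2::labs(x = "Retention time (min)", y = "Intensity") +
      ggplot2::theme_minimal()
  }
}

#' Composition bar chart
#'
#' Relative abundances of identified structures, filled by polymerisation
#' level; structures below `min_pct` are pooled as "other".
#'
#' @param abundances A tibble with `structure` and `abundance_pct` columns,
#'   or a `pg_search_result`.
#' @param min_pct Pooling threshold, percent.
#' @return A ggplot object.
#' @export
plot_composition <- function(abundances, min_pct = 0.5) {
  if (inherits(abundances, "pg_search_result")) abundances <- abundances$consolidated
  d <- dplyr::bind_cols(abundances,
                        classify_structures(abundances$structure)[, "level"])
  d <- d |>
    dplyr::mutate(structure = ifelse(.data$abundance_pct < min_pct, "(other)",
                                     .data$structure)) |>
    dplyr::group_by(.data$structure, .data$level) |>
    dplyr::summarise(abundance_pct = sum(.data$abundance_pct),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$abundance_pct))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$structure, .data$abundance_pct),
    y = .data$abundance_pct, fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = "Level") +
    ggplot2::theme_minimal()
}

#' @rdname plot_chromatogram
#' @param object A `pg_search_result`.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pg_search_result <- function(object, ...) plot_chromatogram(object)
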