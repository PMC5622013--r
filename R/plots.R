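#' Topographic statistical probability map
#'
#' Scatter of electrodes at their schematic head positions; significant
#' electrodes are coloured hot (red, first group prevails) or cold (blue,
#' second group prevails) with intensity graduated on the absolute relative
#' percent difference; non-significant electrodes are hollow.
#'
#' @param object A `stat_map` from [group_map].
#' @param montage Montage tibble providing electrode coordinates.
#' @param ... Unused.
#' @return A ggplot object (facetted by band x direction when present).
#' @export
autoplot.stat_map <- function(object, montage, ...) {
  df <- dplyr::left_join(tibble::as_tibble(object), montage, by = c(electrode = "label"))
  df$signed <- ifelse(df$significant, df$pct_diff, NA_real_)
  labels <- attr(object, "labels") %||% c("A", "B")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      data = df[!df$significant, ],
      shape = 21, size = 3, colour = "grey60", fill = "white"
    ) +
    ggplot2::geom_point(
      data = df[df$significant, ],
      ggplot2::aes(fill = .data$signed), shape = 21, size = 4.5
    ) +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0,
      name = sprintf("%% diff\n(hot = %s)", labels[1])
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s vs %s", labels[1], labels[2]))
  facets <- intersect(c("band", "direction"), names(df))
  facets <- facets[vapply(facets, function(f) any(!is.na(df[[f]])), logical(1))]
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_grid(
      stats::reformulate(
        facets[1], if (length(facets) > 1) facets[2] else "."
      )
    )
  }
  p
}

#' Render a stat map to figure + table
#'
#' @param sm A `stat_map`.
#' @param montage Montage with coordinates.
#' @param path Optional image path (written with [ggplot2::ggsave]).
#' @return List with `figure` (ggplot) and `table` (tibble of significant
#'   electrodes).
#' @export
render_map <- function(sm, montage, path = NULL) {
  fig <- autoplot.stat_map(sm, montage)
  tab <- dplyr::filter(tibble::as_tibble(sm), .data$significant)
  if (!is.null(path)) ggplot2::ggsave(path, fig, width = 7, height = 5)
  list(figure = fig, table = tab)
}

#' Plot an information network on the scalp schematic
#'
#' @param object An `info_network`.
#' @param montage Montage with coordinates (defaults to one matching the
#'   node labels).
#' @param ... Unused.
#' @return A ggplot object: nodes at head positions, directed edges with
#'   width proportional to weight.
#' @export
autoplot.info_network <- function(object, montage = NULL, ...) {
  if (is.null(montage)) montage <- make_montage(length(object$nodes))
  el <- as_edge_list(object)
  coords <- stats::setNames(seq_len(nrow(montage)), montage$label)
  el$x <- montage$x[coords[el$source]]
  el$y <- montage$y[coords[el$source]]
  el$xend <- montage$x[coords[el$target]]
  el$yend <- montage$y[coords[el$target]]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = el,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linewidth = .data$weight
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.6, colour = "steelblue"
    ) +
    ggplot2::geom_point(
      data = montage, ggplot2::aes(x = .data$x, y = .data$y), size = 2
    ) +
    ggplot2::geom_text(
      data = montage, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1, size = 2.5
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
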