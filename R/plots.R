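# ggplot2 views of the result types. These are convenience displays; none of
# the analyses depend on them.

#' @export
autoplot.habitat_score <- function(object, ...) {
  if (!is_mapped(object)) {
    abort("cannot plot an unmapped habitat score")
  }
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, .data$score),
    y = .data$score
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "habitat preference score",
      title = attr(object, "subject_id")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.habitat_score_matrix <- function(object, top_n = 12, ...) {
  categories <- score_categories(object)
  long <- object |>
    dplyr::filter(.data$mapped) |>
    tidyr::pivot_longer(dplyr::all_of(categories),
                        names_to = "category", values_to = "score")
  keep <- long |>
    dplyr::summarise(total = sum(.data$score), .by = "category") |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    dplyr::slice_head(n = top_n)
  long <- long |>
    dplyr::mutate(category = ifelse(.data$category %in% keep$category,
                                    .data$category, "other")) |>
    dplyr::summarise(score = sum(.data$score), .by = c("sample_id", "category"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$score,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "habitat preference score", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.category_network <- function(object, seed = 42, ...) {
  g <- object$graph
  layout <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes |>
    dplyr::mutate(x = layout[, 1], y = layout[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, from = "category", x0 = "x", y0 = "y"),
                     by = "from") |>
    dplyr::left_join(dplyr::select(nodes, to = "category", x1 = "x", y1 = "y"),
                     by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   alpha = 1 - .data$bray_curtis),
      color = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$betweenness),
      color = "#2c7fb8"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$category),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_alpha(range = c(0.15, 0.9), guide = "none") +
    ggplot2::labs(size = "pair-counting\nbetweenness") +
    ggplot2::theme_void()
}
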