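#' Plot an inter-cluster similarity series
#'
#' Line plot of daily inter-cluster similarity per cluster pair, with
#' flagged burst days highlighted when supplied.
#'
#' @param series A `similarity_series` tibble ([cluster_similarity()]).
#' @param flags Optional `burst_flags` tibble ([flag_bursts()]).
#' @param object,x A `similarity_series` (autoplot/plot interface).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_similarity_series <- function(series, flags = NULL) {
  series <- series |>
    mutate(pair = paste(.data$cluster_a, .data$cluster_b, sep = " - "))
  p <- ggplot2::ggplot(
    series,
    ggplot2::aes(x = .data$day, y = .data$similarity, colour = .data$pair)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = NULL, y = "inter-cluster trigram cosine similarity",
      colour = "cluster pair"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(flags) && nrow(flags)) {
    flags <- flags |>
      mutate(pair = paste(.data$cluster_a, .data$cluster_b, sep = " - "))
    p <- p + ggplot2::geom_point(
      data = flags,
      ggplot2::aes(x = .data$day, y = .data$similarity),
      shape = 21, size = 3, stroke = 1
    )
  }
  p
}

#' @rdname plot_similarity_series
#' @export
autoplot.similarity_series <- function(object, ...) {
  plot_similarity_series(object)
}

#' @rdname plot_similarity_series
#' @export
plot.similarity_series <- function(x, ...) print(autoplot(x, ...))

#' Plot linked domain scores and their clustering
#'
#' Dot plot of the community linked-domain scores on the first principal
#' component, colored by score cluster when available.
#'
#' @param score A `domain_score` object.
#' @param clusters Optional `score_clusters` object for coloring.
#' @param object Autoplot interface.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_domain_scores <- function(score, clusters = NULL) {
  df <- score$scores
  if (!is.null(clusters)) {
    df <- df |>
      left_join(
        clusters$clusters |>
          mutate(cluster = factor(.data$cluster)) |>
          select("community", "cluster"),
        by = "community"
      )
  } else {
    df$cluster <- factor(1)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$score, y = stats::reorder(.data$community, .data$score),
      colour = .data$cluster
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "linked domain score (PC1)", y = "community",
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_domain_scores
#' @export
autoplot.domain_score <- function(object, ...) plot_domain_scores(object)

#' Heatmap of scaled per-capita topic rates
#'
#' Greyscale tile plot of scaled per-capita tweet rates, communities on
#' the x axis and topics on the y axis.
#'
#' @param rates A tibble stacking `rate_table`s with an added `topic`
#'   column.
#' @return A ggplot object.
#' @export
plot_rate_heatmap <- function(rates) {
  ggplot2::ggplot(
    rates,
    ggplot2::aes(
      x = .data$community, y = .data$topic, fill = .data$scaled_rate
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "community", y = NULL, fill = "scaled rate") +
    ggplot2::theme_minimal()
}
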