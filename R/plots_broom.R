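#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-modality match
#'
#' @param x An `epi_match`.
#' @param ... Unused.
#' @return Tibble of matched and fallback pairs with a `pair_type` column.
#' @export
tidy.epi_match <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, pair_type = "matched"),
    dplyr::mutate(x$fallback_pairs, pair_type = "fallback")
  )
}

#' @rdname tidy.epi_match
#' @return For `glance`, a one-row tibble of match summary statistics.
#' @export
glance.epi_match <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x$pairs),
    n_fallback = nrow(x$fallback_pairs),
    n_unmatched_row = length(x$unmatched_row),
    n_unmatched_col = length(x$unmatched_col),
    total_cost = x$total_cost,
    mean_cost = mean(x$pairs$cost)
  )
}

#' Tidy fate probabilities into long form
#'
#' @param x An `epi_fates`.
#' @param ... Unused.
#' @return Long tibble `cell_id`, `state`, `probability`.
#' @export
tidy.epi_fates <- function(x, ...) {
  tibble::as_tibble(x$probs, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "state",
                        values_to = "probability")
}

#' @rdname tidy.epi_fates
#' @export
glance.epi_fates <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$probs),
    n_states = length(x$states),
    max_row_sum_error = max(abs(rowSums(x$probs) - 1))
  )
}

#' Tidy a trajectory graph (edge list)
#'
#' @param x An `epi_trajectory_graph`.
#' @param ... Unused.
#' @return Edge tibble with endpoint pseudotime and region columns.
#' @export
tidy.epi_trajectory_graph <- function(x, ...) {
  x$edges |>
    dplyr::left_join(dplyr::rename_with(x$nodes, ~ paste0("from_", .x)),
                     by = c(from = "from_cluster")) |>
    dplyr::left_join(dplyr::rename_with(x$nodes, ~ paste0("to_", .x)),
                     by = c(to = "to_cluster"))
}

#' @rdname tidy.epi_trajectory_graph
#' @export
glance.epi_trajectory_graph <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_regions = length(unique(x$nodes$region))
  )
}

#' Plot a trajectory graph
#'
#' Clusters are placed at (pseudotime, fate-space 1D layout) and joined by
#' the directed edges; color encodes the region label.
#'
#' @param object An `epi_trajectory_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epi_trajectory_graph <- function(object, ...) {
  # 1-D layout within regions spreads branches vertically
  nodes <- object$nodes
  nodes$y <- stats::ave(seq_len(nrow(nodes)), nodes$region, FUN = seq_along) +
    as.integer(factor(nodes$region)) * 2
  edges <- object$edges
  edges$x0 <- nodes$pseudotime[match(edges$from, nodes$cluster)]
  edges$y0 <- nodes$y[match(edges$from, nodes$cluster)]
  edges$x1 <- nodes$pseudotime[match(edges$to, nodes$cluster)]
  edges$y1 <- nodes$y[match(edges$to, nodes$cluster)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$pseudotime, y = .data$y,
                                     color = .data$region), size = 2) +
    ggplot2::labs(x = "pseudotime", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot cells on the circular fate projection
#'
#' @param coords Tibble from [circular_projection()].
#' @param color Optional vector (aligned with rows) mapped to point color,
#'   e.g. a kNN enrichment score or condition.
#' @return A ggplot with the terminal-state anchors drawn on the unit
#'   circle.
#' @export
plot_circular_projection <- function(coords, color = NULL) {
  angles <- attr(coords, "angles")
  anchors <- tibble::tibble(state = names(angles),
                            x = cos(angles), y = sin(angles))
  df <- coords
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(color)) {
    p + ggplot2::geom_point(size = 0.5, alpha = 0.5)
  } else {
    df$color <- color
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$color)) +
      ggplot2::geom_point(size = 0.5, alpha = 0.7)
  }
  p +
    ggplot2::geom_point(data = anchors, ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::geom_text(data = anchors,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$state),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Heatmap of a chromatin-state track
#'
#' @param track An `epi_state_track` from [chromatin_state_track()].
#' @param max_regions Cap on plotted regions (default 200, ordered by first
#'   "on" bin).
#' @return A ggplot tile heatmap of per-bin state labels.
#' @export
plot_state_track <- function(track, max_regions = 200L) {
  lab <- track$labels
  if (nrow(lab) > max_regions) lab <- lab[seq_len(max_regions), , drop = FALSE]
  df <- tibble::as_tibble(lab, rownames = "region") |>
    tidyr::pivot_longer(-"region", names_to = "bin", values_to = "state")
  df$bin <- as.integer(factor(df$bin, levels = colnames(lab)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$region,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "pseudotime bin", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the distribution of recovered pseudotime lags
#'
#' @param lags Tibble from [pseudotime_lag()].
#' @return A ggplot boxplot of lags per chromatin modality.
#' @export
plot_lag_distribution <- function(lags) {
  df <- lags[!is.na(lags$lag), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$lag)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(y = "pseudotime lag (RNA bin - chromatin bin)") +
    ggplot2::theme_minimal()
}
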