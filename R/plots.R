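# ggplot2 displays for the main result types. The analysis functions emit
# the underlying tables; these are convenience views.

#' Plot clonal expansion structure as stacked clone fractions
#'
#' One bar per sample; segments are clones, sized by their fraction of the
#' repertoire, coloured by expansion class.
#'
#' @param clones Clone tibble with expansion classes.
#' @return A ggplot object.
#' @export
plot_clone_fractions <- function(clones) {
  assert_clone_tbl(clones, need_expansion = TRUE)
  df <- clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$size / sum(.data$size)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                   group = .data$clone_id,
                                   fill = .data$expansion_class)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.05) +
    ggplot2::scale_fill_manual(values = c(expanded = "#c0392b",
                                          lowly_expanded = "#bdc3c7")) +
    ggplot2::labs(x = NULL, y = "fraction of repertoire",
                  fill = "expansion") +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise clonal overlap matrix
#'
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(x, ...) {
  df <- tidy(x)
  df <- dplyr::bind_rows(
    df,
    dplyr::rename(df, sample_i = "sample_j", sample_j = "sample_i")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_i, y = .data$sample_j,
                                   fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c3e50") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared clones") +
    ggplot2::theme_minimal()
}

#' Plot a CDR3 similarity network
#'
#' Fruchterman-Reingold layout (via igraph), nodes coloured by group label
#' and sized by clone size.
#'
#' @param x A `tcr_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_network <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for network layout")
  }
  g <- as_igraph(x)
  set.seed(1L) # fixed layout for reproducible figures
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(x$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$node)
  edges <- x$edges |>
    dplyr::mutate(
      x = nodes$x[pos[.data$node_i]], y = nodes$y[pos[.data$node_i]],
      xend = nodes$x[pos[.data$node_j]], yend = nodes$y[pos[.data$node_j]]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.2
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group_label,
                   size = .data$size),
      alpha = 0.8
    ) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::labs(colour = "group", size = "clone size") +
    ggplot2::theme_void()
}

#' Bar chart of V-gene usage frequencies per sample
#'
#' @param usage Usage tibble from [usage_vector()].
#' @return A ggplot object.
#' @export
plot_usage <- function(usage) {
  assert_cols(usage, c("sample_id", "gene", "freq"), "usage table")
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$gene, y = .data$freq,
                                      fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "usage frequency", fill = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked cluster-composition bars for the most expanded clones
#'
#' @param composition Tibble from [clone_cluster_composition()].
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(composition) {
  assert_cols(composition, c("sample_id", "clone_id", "cluster_id",
                             "fraction"), "composition table")
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = stats::reorder(.data$clone_id,
                                                  -.data$size),
                               y = .data$fraction,
                               fill = .data$cluster_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id, scales = "free_x") +
    ggplot2::labs(x = "clone (by expansion rank)", y = "fraction of cells",
                  fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Positional residue-frequency heatmap of a motif matrix
#'
#' @param x A `motif_matrix` or `motif_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_matrix <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", midpoint = 0) +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "CDR3 position", y = NULL, fill = "frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motif_contrast <- autoplot.motif_matrix
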