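# ggplot2 visualisations for the main result types.

#' Plot a target-multiplicity histogram
#'
#' @param hist Tibble (`multiplicity`, `n_genes`) from
#'   [multiplicity_histogram()].
#' @return A ggplot.
#' @export
plot_multiplicity <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$multiplicity),
                                     y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "miRNAs targeting the gene", y = "genes",
                  title = "Target multiplicity") +
    ggplot2::theme_minimal()
}

#' Plot per-miRNA coverage statistics
#'
#' Bar plot of the percentage of the filtered target pool and of all
#' significant DE genes covered by each miRNA.
#'
#' @param coverage Tibble from [coverage_stats()] (or
#'   `tidy(<mir_integration>)`).
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage) {
  long <- tidyr::pivot_longer(coverage, c("pct_of_pool", "pct_of_de"),
                              names_to = "denominator", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mirna_id, y = .data$pct,
                                     fill = .data$denominator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(pct_of_pool = "grey30", pct_of_de = "steelblue"),
      labels = c(pct_of_pool = "% of filtered pool", pct_of_de = "% of DE genes")
    ) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL,
                  title = "Per-miRNA target coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.mir_similarity <- function(object, ...) {
  ord <- cluster_mirnas(object)$order
  ids <- rownames(object$similarity)[ord]
  long <- as_tibble(as.data.frame(as.table(object$distance)),
                    .name_repair = ~c("a", "b", "distance"))
  long$a <- factor(long$a, levels = ids)
  long$b <- factor(long$b, levels = ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - Jaccard",
                  title = "Shared-target distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# segment coordinates for a dendrogram drawn with elbow connectors
dendrogram_segments <- function(hc) {
  n <- length(hc$labels)
  pos <- numeric(n + nrow(hc$merge))
  x_at <- function(code) if (code < 0) match(-code, hc$order) else pos[n + code]
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- x_at(a); xb <- x_at(b)
    ya <- if (a < 0) 0 else hc$height[a]
    yb <- if (b < 0) 0 else hc$height[b]
    h <- hc$height[i]
    pos[n + i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ya, yb, h), yend = c(h, h, h)
    )
  }
  bind_rows(segs)
}

#' @export
autoplot.mir_dendrogram <- function(object, ...) {
  hc <- as.hclust(object)
  segs <- dendrogram_segments(hc)
  leaves <- tibble(x = seq_along(hc$order),
                   label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02,
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous("distance (1 - similarity)",
                                limits = c(-0.5, NA)) +
    ggplot2::labs(x = NULL, title = "miRNA shared-target clustering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @export
autoplot.mir_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "id", "x", "y"), by = c(from = "id")) |>
    left_join(select(nodes, "id", xend = "x", yend = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$relation),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$node_type,
                                     colour = .data$direction),
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            `n/a` = "grey40")) +
    ggplot2::labs(title = "miRNA-target-module network") +
    ggplot2::theme_void()
}
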