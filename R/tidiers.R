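# broom-style tidiers for the fitted/derived objects.

#' Tidy an integration result
#'
#' @param x A `mir_integration` from [integrate_targets()].
#' @param ... Unused.
#' @return Per-miRNA coverage tibble (`mirna_id`, `direction`, `raw_in_de`,
#'   `filtered`, `pct_of_pool`, `pct_of_de`).
#' @export
tidy.mir_integration <- function(x, ...) {
  x$coverage |>
    left_join(select(x$de_mirnas, mirna_id = "feature_id", "direction"),
              by = "mirna_id") |>
    relocate("direction", .after = "mirna_id")
}

#' @rdname tidy.mir_integration
#' @return `glance()` returns a one-row tibble of the headline counts.
#' @export
glance.mir_integration <- function(x, ...) {
  tibble(
    n_de_genes = length(x$de_genes),
    n_de_mirnas = nrow(x$de_mirnas),
    n_mirnas_up = sum(x$de_mirnas$direction == "up"),
    n_mirnas_down = sum(x$de_mirnas$direction == "down"),
    n_predicted_union = length(x$predicted_union),
    n_common = length(x$common),
    n_filtered_pool = length(x$filtered_pool),
    n_filtered_pairs = nrow(x$filtered_pairs),
    q_threshold = x$q_threshold
  )
}

#' Tidy a shared-target similarity object
#'
#' @param x A `mir_similarity` from [pairwise_similarity()].
#' @param ... Unused.
#' @return Long tibble of unordered miRNA pairs with `shared`, `similarity`
#'   and `distance`.
#' @export
tidy.mir_similarity <- function(x, ...) {
  ids <- rownames(x$similarity)
  idx <- which(upper.tri(x$similarity), arr.ind = TRUE)
  tibble(
    mirna_a = ids[idx[, 1]],
    mirna_b = ids[idx[, 2]],
    shared = x$shared[idx],
    similarity = x$similarity[idx],
    distance = x$distance[idx]
  ) |> arrange(.data$mirna_a, .data$mirna_b)
}

#' Tidy a miRNA dendrogram
#'
#' @param x A `mir_dendrogram` from [cluster_mirnas()].
#' @param ... Unused.
#' @return One row per merge: `step`, `height` and the two merged members
#'   (leaf labels, or `#<step>` for prior merges).
#' @export
tidy.mir_dendrogram <- function(x, ...) {
  code_label <- function(code) {
    ifelse(code < 0, x$labels[-pmin(code, -1)], paste0("#", code))
  }
  tibble(
    step = seq_along(x$height),
    member_a = code_label(x$merge[, 1]),
    member_b = code_label(x$merge[, 2]),
    height = x$height
  )
}

#' Tidy a regulatory network
#'
#' @param x A `mir_network` from [build_network()].
#' @param ... Unused.
#' @return The edge tibble; `glance()` returns node/edge counts by type.
#' @export
tidy.mir_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.mir_network
#' @export
glance.mir_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_mirnas = sum(x$nodes$node_type == "miRNA"),
    n_genes = sum(x$nodes$node_type == "gene"),
    n_modules = sum(x$nodes$node_type == "module"),
    n_edges = nrow(x$edges),
    n_targets = sum(x$edges$relation == "targets"),
    n_member_of = sum(x$edges$relation == "member_of")
  )
}
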