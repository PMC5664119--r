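# Functional-module assignment, per-module regulation summaries, the
# tripartite miRNA -> gene -> module regulatory network, and ortholog
# projection.

#' Assign significant genes to functional modules and sub-modules
#'
#' A gene belonging to exactly one base module is assigned there; a gene
#' belonging to k >= 2 base modules is assigned to a derived sub-module named
#' by the sorted `"+"`-join of those module names (e.g.
#' `"NAFLD+Oxidative phosphorylation"`). Genes in no module are left
#' unassigned and excluded from the network.
#'
#' @param modules Long tibble (`module_name`, `gene_id`) from
#'   [read_modules()].
#' @param de_genes Character vector of significant gene identifiers (or a DE
#'   tibble, in which case `feature_id` is used).
#' @return A `mir_module_set`: list with `base_modules` (input, restricted
#'   to DE genes), `assignment` (tibble `gene_id`, `module`, `n_base`) and
#'   `derived_submodules` (character).
#' @export
assign_modules <- function(modules, de_genes) {
  if (is.data.frame(de_genes)) de_genes <- de_genes$feature_id
  base <- modules |>
    distinct(.data$module_name, .data$gene_id) |>
    filter(.data$gene_id %in% de_genes)
  assignment <- base |>
    group_by(.data$gene_id) |>
    summarise(
      module = paste(sort_cx(unique(.data$module_name)), collapse = "+"),
      n_base = n_distinct(.data$module_name),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)
  structure(list(
    base_modules = base,
    module_names = sort_cx(unique(modules$module_name)),
    assignment = assignment,
    derived_submodules = sort_cx(unique(assignment$module[assignment$n_base > 1]))
  ), class = "mir_module_set")
}

#' @export
print.mir_module_set <- function(x, ...) {
  cat("module assignment: ", nrow(x$assignment), " genes, ",
      n_distinct(x$base_modules$module_name), " base modules, ",
      length(x$derived_submodules), " derived sub-modules\n", sep = "")
  invisible(x)
}

#' Per-module regulation direction summary
#'
#' Partitions each module's assigned significant genes by fold-change
#' direction. Base modules with no assigned genes are reported with zero
#' counts and a warning.
#'
#' @param module_set A `mir_module_set` from [assign_modules()].
#' @param de_mrnas Significance-filtered mRNA DE tibble.
#' @return A tibble (`module`, `n_genes`, `n_up`, `n_down`).
#' @export
module_direction_summary <- function(module_set, de_mrnas) {
  dirs <- tibble(
    gene_id = de_mrnas$feature_id,
    direction = classify_direction(de_mrnas$log2_fold_change)
  )
  out <- module_set$assignment |>
    inner_join(dirs, by = "gene_id") |>
    group_by(.data$module) |>
    summarise(
      n_genes = n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
  empty <- setdiff(module_set$module_names, out$module)
  empty <- setdiff(empty,
                   unlist(strsplit(out$module, "+", fixed = TRUE)))
  if (length(empty) > 0) {
    warn(sprintf("module(s) with no assigned significant genes: %s",
                 paste(empty, collapse = ", ")))
    out <- bind_rows(out, tibble(module = empty, n_genes = 0L,
                                 n_up = 0L, n_down = 0L))
  }
  arrange(out, .data$module)
}

new_mir_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "mir_network")
}

#' Build the miRNA-gene-module regulatory network
#'
#' Gene nodes are the module-assigned significant genes; each carries exactly
#' one `member_of` edge to its module (or sub-module) node. `targets` edges
#' are the fold-change-sign-consistent retained pairs restricted to those
#' genes. miRNA nodes are the DE miRNAs with at least one such edge, unless
#' `keep_isolated_mirnas` is set.
#'
#' @param module_set A `mir_module_set` from [assign_modules()].
#' @param filtered_pairs Retained pairs from [anticorrelation_filter()].
#' @param de_mirnas Significance-filtered miRNA DE tibble.
#' @param de_mrnas Significance-filtered mRNA DE tibble.
#' @param keep_isolated_mirnas Keep DE miRNAs with no retained module target
#'   as isolated nodes; default drops them.
#' @return A `mir_network`: list of `nodes` (`id`, `node_type`, `direction`,
#'   `log2_fold_change`, `targeted`) and `edges` (`from`, `to`, `relation`).
#' @export
build_network <- function(module_set, filtered_pairs, de_mirnas, de_mrnas,
                          keep_isolated_mirnas = FALSE) {
  assignment <- module_set$assignment
  gene_ids <- assignment$gene_id
  target_edges <- filtered_pairs |>
    filter(.data$gene_id %in% gene_ids) |>
    transmute(from = .data$mirna_id, to = .data$gene_id,
              relation = "targets")
  member_edges <- transmute(assignment, from = .data$gene_id,
                            to = .data$module, relation = "member_of")

  mirna_tbl <- classify_direction(de_mirnas)
  if (!keep_isolated_mirnas) {
    mirna_tbl <- filter(mirna_tbl, .data$feature_id %in% target_edges$from)
  }
  gene_tbl <- de_mrnas |>
    filter(.data$feature_id %in% gene_ids) |>
    classify_direction()

  nodes <- bind_rows(
    tibble(id = mirna_tbl$feature_id, node_type = "miRNA",
           direction = mirna_tbl$direction,
           log2_fold_change = mirna_tbl$log2_fold_change,
           targeted = NA),
    tibble(id = gene_tbl$feature_id, node_type = "gene",
           direction = gene_tbl$direction,
           log2_fold_change = gene_tbl$log2_fold_change,
           targeted = gene_tbl$feature_id %in% target_edges$to),
    tibble(id = sort_cx(unique(assignment$module)), node_type = "module",
           direction = "n/a", log2_fold_change = NA_real_, targeted = NA)
  ) |> arrange(.data$node_type, .data$id)

  edges <- bind_rows(target_edges, member_edges) |>
    arrange(.data$relation, .data$from, .data$to)
  new_mir_network(nodes, edges)
}

#' @export
print.mir_network <- function(x, ...) {
  tt <- table(x$nodes$node_type)
  cat("regulatory network: ", nrow(x$nodes), " nodes (",
      paste(names(tt), tt, sep = ": ", collapse = ", "), "), ",
      nrow(x$edges), " edges (",
      sum(x$edges$relation == "targets"), " targets, ",
      sum(x$edges$relation == "member_of"), " member_of)\n", sep = "")
  invisible(x)
}

#' Project gene identifiers onto orthologs
#'
#' Left-joins an ortholog map onto a DE gene table, appending an
#' `ortholog_id` column; genes without an ortholog are retained with `NA`
#' and counted.
#'
#' @param de_mrnas DE tibble (or any tibble with `feature_id`).
#' @param ortholog_map Tibble (`source_id`, `target_id`) from
#'   [read_ortholog_map()].
#' @return The input tibble with an `ortholog_id` column; attributes
#'   `n_mapped` and `n_unmapped` carry the join counts.
#' @export
project_orthologs <- function(de_mrnas, ortholog_map) {
  out <- de_mrnas |>
    left_join(
      tibble(feature_id = ortholog_map$source_id,
             ortholog_id = ortholog_map$target_id),
      by = "feature_id"
    )
  n_mapped <- sum(!is.na(out$ortholog_id))
  n_unmapped <- nrow(out) - n_mapped
  inform(sprintf("ortholog projection: %d mapped, %d unmapped",
                 n_mapped, n_unmapped))
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_unmapped") <- n_unmapped
  out
}
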