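# Writers (and matching readers) for the pipeline's artifacts: incidence
# matrix, multiplicity histogram, similarity matrices as TSV; dendrogram as
# Newick; network as SIF + GraphML. Writers emit stable row/column orderings
# so identical runs are byte-identical.

#' Write / read a binary incidence matrix as TSV
#'
#' The first column (`mirna_id`) holds row names; remaining columns are gene
#' identifiers with 0/1 cells. Orderings are preserved as stored in the
#' matrix.
#'
#' @param mat Binary matrix with miRNA rownames and gene colnames, as built
#'   by [build_incidence()].
#' @param path Output path.
#' @return `write_incidence_matrix()` returns `path` invisibly;
#'   `read_incidence_matrix()` returns the integer matrix.
#' @export
write_incidence_matrix <- function(mat, path) {
  tbl <- as_tibble(as.data.frame(mat, check.names = FALSE))
  tbl <- bind_cols(tibble(mirna_id = rownames(mat) %||% character(0)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_incidence_matrix
#' @export
read_incidence_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- tbl$mirna_id
  mat
}

#' Write / read a target-multiplicity histogram as TSV
#'
#' @param hist A tibble with columns `multiplicity`, `n_genes`, as returned
#'   by [multiplicity_histogram()].
#' @param path Output path.
#' @return `path` invisibly; the reader returns the tibble with the
#'   `n_multi_targeted` attribute restored.
#' @export
write_histogram <- function(hist, path) {
  readr::write_tsv(hist[, c("multiplicity", "n_genes")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  out <- readr::read_tsv(path, col_types = "ii", progress = FALSE)
  attr(out, "n_multi_targeted") <-
    sum(out$n_genes[out$multiplicity >= 2])
  out
}

#' Write / read a square similarity (or shared-count) matrix as TSV
#'
#' @param mat A square numeric matrix with identical row and column names, or
#'   a `mir_similarity` object (its `similarity` component is written).
#' @param path Output path.
#' @return `path` invisibly; the reader returns the numeric matrix.
#' @export
write_similarity <- function(mat, path) {
  if (inherits(mat, "mir_similarity")) mat <- mat$similarity
  tbl <- as_tibble(as.data.frame(mat, check.names = FALSE))
  tbl <- bind_cols(tibble(mirna_id = rownames(mat) %||% character(0)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl$mirna_id
  mat
}

# Quote a Newick label when it contains characters reserved by the format.
quote_newick_label <- function(x) {
  unsafe <- grepl("[][()'\",;:[:space:]]", x)
  x[unsafe] <- paste0("'", gsub("'", "''", x[unsafe]), "'")
  x
}

#' Serialize a miRNA dendrogram to Newick
#'
#' Branch lengths are derived from merge heights (ultrametric tree). A
#' single-leaf tree is written as `(leaf:0);`.
#'
#' @param dend A `mir_dendrogram` from [cluster_mirnas()], or an `hclust`.
#' @return A single Newick string.
#' @export
as_newick <- function(dend) {
  if (inherits(dend, "mir_dendrogram") && length(dend$labels) == 1) {
    return(paste0("(", quote_newick_label(dend$labels), ":0);"))
  }
  hc <- as.hclust(dend)
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' @rdname as_newick
#' @param path Output path for the Newick file.
#' @export
write_dendrogram <- function(dend, path) {
  writeLines(as_newick(dend), path)
  invisible(path)
}

#' Export a regulatory network
#'
#' `write_network_sif()` writes the simple-interaction format consumed by
#' Cytoscape, one edge per line (`source  relation  target`); relations are
#' `targets` (miRNA to gene) and `member_of` (gene to module).
#' `write_network_graphml()` writes GraphML with node attributes
#' `node_type`, `direction`, `log2_fold_change`, `targeted` and edge
#' attribute `relation`. `read_network_graphml()` restores a
#' [mir_network][build_network()] from such a file.
#'
#' @param net A `mir_network` object from [build_network()].
#' @param path Output path.
#' @return `path` invisibly; the reader returns a `mir_network`.
#' @export
write_network_sif <- function(net, path) {
  edges <- arrange(net$edges, .data$relation, .data$from, .data$to)
  writeLines(paste(edges$from, edges$relation, edges$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_sif
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(
    id = igraph::V(g)$name,
    node_type = igraph::V(g)$node_type,
    direction = igraph::V(g)$direction,
    log2_fold_change = ifelse(is.nan(igraph::V(g)$log2_fold_change),
                              NA_real_, igraph::V(g)$log2_fold_change),
    targeted = as.logical(igraph::V(g)$targeted)
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    from = el[, 1], to = el[, 2],
    relation = igraph::E(g)$relation
  )
  new_mir_network(nodes, edges)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param net A `mir_network` object.
#' @return An igraph directed graph with typed nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mir_network"))
  vertices <- as.data.frame(net$nodes)
  vertices$log2_fold_change <- as.numeric(vertices$log2_fold_change)
  igraph::graph_from_data_frame(
    as.data.frame(net$edges[, c("from", "to", "relation")]),
    directed = TRUE, vertices = vertices
  )
}
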