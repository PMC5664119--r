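# miRNA x gene incidence matrix, target-multiplicity histogram, shared-target
# Jaccard similarity and agglomerative miRNA clustering with deterministic
# tie-breaking.

#' Build the binary miRNA-by-gene incidence matrix
#'
#' One row per miRNA (first-appearance order of `filtered_pairs`, or
#' `mirna_order` when given), one column per gene (C-locale lexicographic),
#' cell 1 iff the pair survived the anti-correlation filter. Genes enter only
#' through retained pairs, so no gene column is all-zero.
#'
#' @param filtered_pairs Retained pairs from [anticorrelation_filter()].
#' @param mirna_order Optional character vector fixing row order (miRNAs
#'   without retained pairs get all-zero rows).
#' @return Integer 0/1 matrix with miRNA rownames and gene colnames.
#' @export
build_incidence <- function(filtered_pairs, mirna_order = NULL) {
  mirnas <- mirna_order %||% unique(filtered_pairs$mirna_id)
  genes <- sort_cx(unique(filtered_pairs$gene_id))
  if (length(genes) == 0) {
    warn("no retained pairs: incidence matrix has zero gene columns")
  }
  mat <- matrix(0L, nrow = length(mirnas), ncol = length(genes),
                dimnames = list(mirnas, genes))
  if (nrow(filtered_pairs) > 0) {
    mat[cbind(match(filtered_pairs$mirna_id, mirnas),
              match(filtered_pairs$gene_id, genes))] <- 1L
  }
  mat
}

#' Target-multiplicity histogram
#'
#' Counts, for each multiplicity k, how many genes are targeted by exactly k
#' miRNAs (column sums of the incidence matrix). The number of genes targeted
#' by more than one miRNA is attached as attribute `n_multi_targeted`.
#'
#' @param matrix Incidence matrix from [build_incidence()].
#' @return A tibble (`multiplicity`, `n_genes`), ascending multiplicity.
#' @export
multiplicity_histogram <- function(matrix) {
  mult <- colSums(matrix)
  tab <- table(mult[mult > 0])
  out <- tibble(
    multiplicity = as.integer(names(tab)),
    n_genes = as.integer(tab)
  ) |> arrange(.data$multiplicity)
  attr(out, "n_multi_targeted") <- sum(out$n_genes[out$multiplicity >= 2])
  out
}

#' Count of genes targeted by more than one miRNA
#'
#' @param x A multiplicity histogram tibble or an incidence matrix.
#' @return Integer count of genes with multiplicity >= 2.
#' @export
multi_targeted_count <- function(x) {
  if (is.matrix(x)) x <- multiplicity_histogram(x)
  sum(x$n_genes[x$multiplicity >= 2])
}

#' Pairwise shared-target similarity between miRNAs
#'
#' Jaccard similarity of the target sets of every miRNA pair:
#' `|T_a intersect T_b| / |T_a union T_b|`. Two empty target sets get
#' similarity 0 (no evidence of similarity) with a warning. The clustering
#' distance is `1 - similarity`, so a miRNA whose targets are disjoint from
#' all others sits at distance exactly 1 from everything.
#'
#' @param matrix Incidence matrix with at least two rows.
#' @param metric Similarity metric; only `"jaccard"` is implemented.
#' @return A `mir_similarity` object: list with square matrices
#'   `similarity`, `shared` (intersection counts), `distance`, and `metric`.
#' @export
pairwise_similarity <- function(matrix, metric = c("jaccard")) {
  metric <- match.arg(metric)
  if (nrow(matrix) < 2) {
    stop_degenerate("similarity requires at least two miRNAs")
  }
  m <- matrix
  storage.mode(m) <- "double"
  shared <- m %*% t(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - shared
  sim <- shared / union
  if (any(union == 0)) {
    warn("miRNA pair(s) with two empty target sets: similarity set to 0")
    sim[union == 0] <- 0
  }
  diag(sim) <- 1
  storage.mode(shared) <- "integer"
  structure(list(similarity = sim, shared = shared, distance = 1 - sim,
                 metric = metric), class = "mir_similarity")
}

#' @export
print.mir_similarity <- function(x, ...) {
  cat("shared-target similarity (", x$metric, ") over ",
      nrow(x$similarity), " miRNAs\n", sep = "")
  invisible(x)
}

# lexicographically compare two representative pairs (a1,a2) < (b1,b2),
# C-locale, so tie-breaking is platform independent
pair_lt <- function(a, b) {
  if (a[1] != b[1]) return(identical(sort_cx(c(a[1], b[1]))[1], a[1]))
  a[2] != b[2] && identical(sort_cx(c(a[2], b[2]))[1], a[2])
}

#' Cluster miRNAs by shared-target distance
#'
#' Agglomerative hierarchical clustering on `1 - similarity`. Ties in the
#' minimal inter-cluster distance are broken deterministically in favour of
#' the pair whose (sorted) representative leaf labels are lexicographically
#' smallest; leaf order puts the subtree containing the smallest label first.
#'
#' @param similarity A `mir_similarity` object or a symmetric similarity
#'   matrix with unit diagonal.
#' @param linkage `"average"` (UPGMA, default), `"complete"`, or `"ward"`
#'   (Lance-Williams update of squared distances, as in Ward.D2).
#' @return A `mir_dendrogram`: list with hclust-style `merge`, `height`,
#'   `order`, `labels`, plus `linkage`. Convert with [as.hclust()] or
#'   [as_newick()].
#' @export
cluster_mirnas <- function(similarity, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  sim <- if (inherits(similarity, "mir_similarity")) similarity$similarity else similarity
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-10))) {
    stop_validation("similarity matrix is not symmetric")
  }
  n <- nrow(sim)
  if (n < 2) stop_degenerate("clustering requires at least two miRNAs")
  labels <- rownames(sim) %||% as.character(seq_len(n))
  D <- 1 - sim
  diag(D) <- 0

  active <- seq_len(n)
  node <- -seq_len(n)            # hclust codes: negative leaves
  rep_lab <- labels              # smallest leaf label per cluster
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  children <- vector("list", n - 1)

  for (step in seq_len(n - 1)) {
    # minimal distance among active clusters, deterministic tie-break
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        d <- D[a, b]
        reps <- sort_cx(c(rep_lab[a], rep_lab[b]))
        if (d < best_d - 1e-12 ||
              (abs(d - best_d) <= 1e-12 && pair_lt(reps, best$reps))) {
          best <- list(a = a, b = b, reps = reps)
          best_d <- d
        }
      }
    }
    a <- best$a; b <- best$b
    height[step] <- best_d
    merge[step, ] <- sort(c(node[a], node[b]))
    children[[step]] <- c(node[a], node[b])

    # Lance-Williams update into slot a; retire slot b
    for (k in setdiff(active, c(a, b))) {
      D[a, k] <- D[k, a] <- switch(linkage,
        average = (sizes[a] * D[a, k] + sizes[b] * D[b, k]) /
          (sizes[a] + sizes[b]),
        complete = max(D[a, k], D[b, k]),
        ward = sqrt(((sizes[a] + sizes[k]) * D[a, k]^2 +
                       (sizes[b] + sizes[k]) * D[b, k]^2 -
                       sizes[k] * best_d^2) /
                      (sizes[a] + sizes[b] + sizes[k]))
      )
    }
    sizes[a] <- sizes[a] + sizes[b]
    rep_lab[a] <- sort_cx(c(rep_lab[a], rep_lab[b]))[1]
    node[a] <- step
    active <- setdiff(active, b)
  }

  # leaf order: recursive, subtree holding the smallest label first
  smallest <- function(code) {
    if (code < 0) labels[-code] else {
      sort_cx(c(smallest(children[[code]][1]), smallest(children[[code]][2])))[1]
    }
  }
  leaves <- function(code) {
    if (code < 0) return(-code)
    ch <- children[[code]]
    s1 <- smallest(ch[1]); s2 <- smallest(ch[2])
    if (identical(sort_cx(c(s1, s2))[1], s1)) {
      c(leaves(ch[1]), leaves(ch[2]))
    } else {
      c(leaves(ch[2]), leaves(ch[1]))
    }
  }
  structure(list(
    merge = merge, height = height, order = leaves(n - 1L),
    labels = labels, linkage = linkage
  ), class = "mir_dendrogram")
}

#' @export
as.hclust.mir_dendrogram <- function(x, ...) {
  structure(list(
    merge = x$merge, height = x$height, order = x$order, labels = x$labels,
    method = x$linkage, call = match.call(), dist.method = "1 - jaccard"
  ), class = "hclust")
}

#' @export
print.mir_dendrogram <- function(x, ...) {
  cat("miRNA shared-target dendrogram (", x$linkage, " linkage, ",
      length(x$labels), " leaves)\n", sep = "")
  invisible(x)
}

#' Ward/Euclidean ordering for expression heatmaps
#'
#' Orders rows and columns of a gene-by-sample value matrix by agglomerative
#' Ward clustering on Euclidean distances, the conventional setting for DE
#' heatmaps. Values may be pre-normalized (e.g. a variance-stabilized
#' transform); otherwise a `log2(x + 1)` transform is applied.
#'
#' @param values Numeric matrix (genes x samples), finite.
#' @param normalize `"log2"` (default, applies `log2(x + 1)`) or `"none"`.
#' @return A list with `row_order`, `col_order` (integer permutations) and
#'   the underlying `row_tree`, `col_tree` (`hclust` objects).
#' @export
heatmap_order <- function(values, normalize = c("log2", "none")) {
  normalize <- match.arg(normalize)
  if (!all(is.finite(values))) stop_validation("values must be finite")
  x <- if (normalize == "log2") log2(values + 1) else values
  if (diff(range(x)) == 0) {
    warn("constant matrix: all distances zero, single flat cluster")
  }
  row_tree <- hclust(dist(x), method = "ward.D2")
  col_tree <- hclust(dist(t(x)), method = "ward.D2")
  list(row_order = row_tree$order, col_order = col_tree$order,
       row_tree = row_tree, col_tree = col_tree)
}
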