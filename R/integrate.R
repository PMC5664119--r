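# Target integration: intersect predicted targets with significant DE genes,
# apply the anti-correlation fold-change criterion, and compute per-miRNA
# coverage statistics.

#' Intersect predicted targets with significant DE genes
#'
#' The predicted-target universe is the deduplicated union of targets over
#' the supplied (DE) miRNAs' predictions; it is intersected with the
#' significant gene set of the mRNA DE table.
#'
#' @param predictions Prediction tibble (`mirna_id`, `gene_id`), already
#'   restricted to the miRNAs of interest and deduplicated.
#' @param de_mrnas Significance-filtered mRNA DE tibble.
#' @return A list: `predicted_union`, `de_genes`, `common` (character
#'   vectors, C-locale sorted) and `venn_counts`, a one-row tibble
#'   (`predicted_only`, `common`, `de_only`).
#' @export
intersect_targets <- function(predictions, de_mrnas) {
  predicted_union <- sort_cx(unique(predictions$gene_id))
  de_genes <- sort_cx(unique(de_mrnas$feature_id))
  common <- intersect(predicted_union, de_genes)
  n_common <- length(common)
  list(
    predicted_union = predicted_union,
    de_genes = de_genes,
    common = common,
    venn_counts = tibble(
      predicted_only = length(predicted_union) - n_common,
      common = n_common,
      de_only = length(de_genes) - n_common
    )
  )
}

#' Anti-correlation fold-change filter
#'
#' Retains a predicted pair (miRNA, gene) only when the gene is in the
#' common set and its log2 fold-change sign is opposite to the miRNA's
#' direction, reflecting miRNA-mediated silencing: targets of up-regulated
#' miRNAs must be down-regulated and vice versa. Genes with a fold change of
#' exactly zero are never retained.
#'
#' @param common Character vector of genes common to predictions and the
#'   significant DE gene set.
#' @param de_mrnas Significance-filtered mRNA DE tibble.
#' @param de_mirnas Significance-filtered miRNA DE tibble; every miRNA must
#'   have a non-zero fold change.
#' @param predictions Prediction tibble (`mirna_id`, `gene_id`).
#' @return A tibble of retained pairs: `mirna_id`, `gene_id`,
#'   `mirna_direction`, `gene_log2fc`.
#' @export
anticorrelation_filter <- function(common, de_mrnas, de_mirnas, predictions) {
  mir_dir <- classify_direction(de_mirnas$log2_fold_change)
  if (any(is.na(mir_dir) | mir_dir == "unchanged")) {
    bad <- de_mirnas$feature_id[is.na(mir_dir) | mir_dir == "unchanged"]
    stop_validation(sprintf(
      "DE miRNAs with direction 'unchanged' (log2FC = 0): %s",
      paste(bad, collapse = ", ")))
  }
  dirs <- tibble(mirna_id = de_mirnas$feature_id, mirna_direction = mir_dir)
  fc <- tibble(gene_id = de_mrnas$feature_id,
               gene_log2fc = de_mrnas$log2_fold_change)

  predictions |>
    filter(.data$mirna_id %in% dirs$mirna_id, .data$gene_id %in% common) |>
    inner_join(dirs, by = "mirna_id") |>
    inner_join(fc, by = "gene_id") |>
    filter((.data$mirna_direction == "up" & .data$gene_log2fc < 0) |
             (.data$mirna_direction == "down" & .data$gene_log2fc > 0)) |>
    select("mirna_id", "gene_id", "mirna_direction", "gene_log2fc") |>
    arrange(.data$mirna_id, .data$gene_id)
}

#' Per-miRNA coverage statistics
#'
#' For each DE miRNA: the number of its predicted targets present in the
#' significant DE gene set (`raw_in_de`), the number surviving the
#' anti-correlation filter (`filtered`), that count as a percentage of the
#' filtered target pool (`pct_of_pool`) and of all significant DE genes
#' (`pct_of_de`). Percentages are rounded half-even to one decimal.
#'
#' @param filtered_pairs Retained pairs from [anticorrelation_filter()].
#' @param predictions Prediction tibble for the DE miRNAs.
#' @param de_mirnas Significance-filtered miRNA DE tibble.
#' @param de_genes Character vector of significant DE gene identifiers.
#' @param filtered_pool Character vector: union of retained genes.
#' @return A tibble with one row per DE miRNA.
#' @export
coverage_stats <- function(filtered_pairs, predictions, de_mirnas, de_genes,
                           filtered_pool) {
  n_pool <- length(filtered_pool)
  n_de <- length(de_genes)
  if (n_pool == 0) {
    warn("filtered pool is empty; coverage percentages reported as 0")
  }
  raw <- predictions |>
    filter(.data$gene_id %in% de_genes) |>
    count(.data$mirna_id, name = "raw_in_de")
  flt <- count(filtered_pairs, .data$mirna_id, name = "filtered")
  tibble(mirna_id = de_mirnas$feature_id) |>
    left_join(raw, by = "mirna_id") |>
    left_join(flt, by = "mirna_id") |>
    mutate(
      raw_in_de = coalesce(.data$raw_in_de, 0L),
      filtered = coalesce(.data$filtered, 0L),
      pct_of_pool = if (n_pool > 0) round(100 * .data$filtered / n_pool, 1) else 0,
      pct_of_de = if (n_de > 0) round(100 * .data$filtered / n_de, 1) else 0
    )
}

#' Integrate miRNA and mRNA differential-expression results
#'
#' End-to-end integration step: filters both DE tables at `q_threshold`,
#' restricts predictions to the significant miRNAs, intersects the predicted
#' target union with the significant genes, applies the anti-correlation
#' fold-change criterion and computes per-miRNA coverage.
#'
#' @param mrna_de,mirna_de DE tibbles as returned by [read_de_table()].
#' @param predictions Prediction tibble (`mirna_id`, `gene_id`).
#' @param q_threshold Significance cut (inclusive); default 0.1.
#' @param readjust Recompute q-values from p-values before filtering.
#' @return A `mir_integration` object: list with `de_genes`, `de_mirnas`
#'   (tibble with `direction`), `predicted_union`, `common`,
#'   `filtered_pairs`, `filtered_pool`, `venn_counts`, `coverage`.
#' @seealso [tidy.mir_integration()], [glance.mir_integration()]
#' @export
integrate_targets <- function(mrna_de, mirna_de, predictions,
                              q_threshold = 0.1, readjust = FALSE) {
  sig_mrna <- filter_significant(mrna_de, q_threshold, readjust)
  sig_mirna <- filter_significant(mirna_de, q_threshold, readjust)
  preds <- predictions |>
    distinct(.data$mirna_id, .data$gene_id) |>
    filter(.data$mirna_id %in% sig_mirna$feature_id)

  inter <- intersect_targets(preds, sig_mrna)
  pairs <- anticorrelation_filter(inter$common, sig_mrna, sig_mirna, preds)
  pool <- sort_cx(unique(pairs$gene_id))
  cov <- coverage_stats(pairs, preds, sig_mirna, inter$de_genes, pool)

  structure(list(
    de_genes = inter$de_genes,
    de_mirnas = classify_direction(sig_mirna),
    predicted_union = inter$predicted_union,
    common = inter$common,
    filtered_pairs = pairs,
    filtered_pool = pool,
    venn_counts = inter$venn_counts,
    coverage = cov,
    q_threshold = q_threshold
  ), class = "mir_integration")
}

#' @export
print.mir_integration <- function(x, ...) {
  cat("miRNA-mRNA target integration (q <= ", x$q_threshold, ")\n", sep = "")
  cat("  significant mRNAs:        ", length(x$de_genes), "\n", sep = "")
  cat("  significant miRNAs:       ", nrow(x$de_mirnas),
      " (", sum(x$de_mirnas$direction == "up"), " up, ",
      sum(x$de_mirnas$direction == "down"), " down)\n", sep = "")
  cat("  predicted target union:   ", length(x$predicted_union), "\n", sep = "")
  cat("  common (predicted & DE):  ", length(x$common), "\n", sep = "")
  cat("  anti-correlated pool:     ", length(x$filtered_pool), "\n", sep = "")
  cat("  retained (miRNA, gene) pairs: ", nrow(x$filtered_pairs), "\n", sep = "")
  invisible(x)
}
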