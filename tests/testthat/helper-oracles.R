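# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (loops, exhaustive enumeration) so they cannot share a
# defect with the vectorised implementations they check.

# Benjamini-Hochberg step-up, written from the definition: on sorted
# p-values, q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, ps[j] * m / j)
    q[i] <- min(1, vals)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Jaccard similarity of two index sets, by direct set counting.
jaccard_oracle <- function(a, b) {
  if (length(union(a, b)) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

# A random binary incidence matrix with named rows/columns.
random_incidence <- function(n_mirnas, n_genes, density = 0.3) {
  mat <- matrix(as.integer(runif(n_mirnas * n_genes) < density),
                n_mirnas, n_genes,
                dimnames = list(sprintf("m%02d", seq_len(n_mirnas)),
                                sprintf("g%03d", seq_len(n_genes))))
  mat
}

# Exhaustive node/edge counts for the regulatory network: loop over every
# (miRNA, gene) combination and every assignment row.
network_counts_oracle <- function(assignment, filtered_pairs, de_mirnas) {
  pair_key <- paste(filtered_pairs$mirna_id, filtered_pairs$gene_id)
  n_targets <- 0L
  mirnas_with_edge <- character(0)
  for (m in de_mirnas$feature_id) {
    for (g in assignment$gene_id) {
      if (paste(m, g) %in% pair_key) {
        n_targets <- n_targets + 1L
        mirnas_with_edge <- union(mirnas_with_edge, m)
      }
    }
  }
  list(
    n_mirnas = length(mirnas_with_edge),
    n_genes = nrow(assignment),
    n_modules = length(unique(assignment$module)),
    n_targets = n_targets,
    n_member_of = nrow(assignment),
    n_edges = n_targets + nrow(assignment)
  )
}

# Minimal DE tibble builder for hand-made cases.
de_tbl <- function(ids, lfc, q = 0.01, p = q / 10) {
  tibble::tibble(
    feature_id = ids, base_mean = 100,
    log2_fold_change = lfc, p_value = p, q_value = q
  )
}

write_tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
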