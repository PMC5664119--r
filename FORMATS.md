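# File format contract

All tabular I/O is TSV with exactly one header line, UTF-8, unquoted fields.
Column names on *input* are resolved case-insensitively through the alias map
(`de_column_aliases()`); *output* always uses the canonical names below, in
the stated order. Identifiers are compared case-sensitively after trimming
surrounding whitespace.

## Inputs

### DE result table (mRNA or miRNA)
Canonical columns, in order:

    feature_id  base_mean  log2_fold_change  p_value  q_value

Accepted aliases include `id`/`gene_id`/`symbol`, `baseMean`,
`log2FoldChange`/`logFC`, `pvalue`/`p`, `padj`/`qvalue`/`FDR`.
Constraints: unique non-empty `feature_id`; `p_value`, `q_value` in [0, 1];
`base_mean >= 0`.

### Target predictions

    mirna_id  gene_id  [site_annotation]

Duplicated (mirna_id, gene_id) pairs are collapsed on read (count logged).

### Module definitions (long format)

    module_name  gene_id

A gene may appear under several modules.

### Ortholog map

    source_id  target_id

One row per source id after reading; conflicting rows keep the first
occurrence (logged).

## Outputs (written by `run_pipeline()` and the writers)

| file | columns / format |
|---|---|
| `significant_mrna.tsv`, `significant_mirna.tsv` | DE canonical columns (+ `direction` for miRNAs) |
| `venn_counts.tsv` | `predicted_only  common  de_only` |
| `filtered_pairs.tsv` | `mirna_id  gene_id  mirna_direction  gene_log2fc`, sorted by miRNA then gene |
| `coverage_stats.tsv` | `mirna_id  raw_in_de  filtered  pct_of_pool  pct_of_de` |
| `incidence.tsv` | first column `mirna_id`, then one 0/1 column per gene (row order: miRNA input order; column order: C-locale lexicographic) |
| `histogram.tsv` | `multiplicity  n_genes`, ascending |
| `similarity.tsv`, `shared_counts.tsv` | square matrix, first column `mirna_id` |
| `dendrogram.nwk` | Newick, ultrametric branch lengths from merge heights; single leaf as `(leaf:0);`; labels with reserved characters single-quoted |
| `network.sif` | `source <TAB> relation <TAB> target`; relations `targets` (miRNA -> gene) and `member_of` (gene -> module) |
| `network.graphml` | GraphML; node attributes `node_type`, `direction`, `log2_fold_change`, `targeted`; edge attribute `relation` |
| `module_summary.tsv` | `module  n_genes  n_up  n_down` |
| `humanized_genes.tsv` | DE canonical columns + `ortholog_id` (empty when unmapped) |
| `run_report.json` | stage counts, config echo, seed, version |

Writers emit stable orderings, so reruns on identical inputs are
byte-identical (`run_report.json` carries no timestamp unless requested).
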