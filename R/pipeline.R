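# End-to-end orchestration: filter -> integrate -> matrix/cluster -> network,
# with all stage artifacts written to an output directory and a
# machine-readable run report whose every count is re-derivable from the
# artifacts.

read_if_path <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "mirtarnet_stage_error", stage = stage, parent = e)
  })
}

#' Run the full miRNA-mRNA integration pipeline
#'
#' Executes the stages in order -- significance filtering, target
#' integration, incidence matrix / multiplicity histogram, shared-target
#' clustering, module network, optional ortholog projection -- writing every
#' stage artifact to `out_dir` plus a JSON run report. Reruns with identical
#' inputs are byte-identical (no timestamp is written unless requested).
#'
#' @param mrna_de,mirna_de DE tables: tibbles or TSV paths.
#' @param predictions Prediction table: tibble or TSV path.
#' @param modules Optional module definitions: tibble or TSV path.
#' @param ortholog_map Optional ortholog map: tibble or TSV path.
#' @param out_dir Output directory, created if missing.
#' @param q_threshold Significance cut (inclusive), default 0.1.
#' @param readjust Recompute q-values from p-values before filtering.
#' @param metric Similarity metric for miRNA clustering.
#' @param linkage Linkage for miRNA clustering.
#' @param keep_isolated_mirnas Keep DE miRNAs without module targets as
#'   isolated network nodes.
#' @param seed Echoed into the report (the pipeline itself draws no random
#'   numbers).
#' @param include_timestamp Add a timestamp to the report (breaks
#'   byte-identical reruns; off by default).
#' @return The run report (list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(mrna_de, mirna_de, predictions,
                         modules = NULL, ortholog_map = NULL,
                         out_dir = ".", q_threshold = 0.1, readjust = FALSE,
                         metric = "jaccard", linkage = "average",
                         keep_isolated_mirnas = FALSE, seed = NULL,
                         include_timestamp = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  mrna_de <- run_stage("read", read_if_path(mrna_de, read_de_table, "mRNA"))
  mirna_de <- run_stage("read", read_if_path(mirna_de, read_de_table, "miRNA"))
  predictions <- run_stage("read",
                           read_if_path(predictions, read_target_predictions))
  if (!is.null(modules)) {
    modules <- run_stage("read", read_if_path(modules, read_modules))
  }
  if (!is.null(ortholog_map)) {
    ortholog_map <- run_stage("read",
                              read_if_path(ortholog_map, read_ortholog_map))
  }
  n_input <- list(mrna = nrow(mrna_de), mirna = nrow(mirna_de),
                  predictions = nrow(predictions))

  integration <- run_stage("integrate",
    integrate_targets(mrna_de, mirna_de, predictions,
                      q_threshold = q_threshold, readjust = readjust))
  sig_mrna <- filter(mrna_de, !is.na(.data$q_value),
                     .data$q_value <= q_threshold)
  if (isTRUE(readjust)) {
    sig_mrna <- filter(mutate(mrna_de, q_value = bh_adjust(.data$p_value)),
                       .data$q_value <= q_threshold)
  }
  readr::write_tsv(sig_mrna, p("significant_mrna.tsv"), progress = FALSE)
  readr::write_tsv(integration$de_mirnas, p("significant_mirna.tsv"),
                   progress = FALSE)
  readr::write_tsv(integration$venn_counts, p("venn_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(integration$filtered_pairs, p("filtered_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(integration$coverage, p("coverage_stats.tsv"),
                   progress = FALSE)

  incidence <- run_stage("matrix",
    build_incidence(integration$filtered_pairs,
                    mirna_order = integration$de_mirnas$feature_id))
  histogram <- run_stage("matrix", multiplicity_histogram(incidence))
  write_incidence_matrix(incidence, p("incidence.tsv"))
  write_histogram(histogram, p("histogram.tsv"))

  dend <- NULL
  if (nrow(incidence) >= 2 && ncol(incidence) >= 1) {
    sim <- run_stage("cluster", pairwise_similarity(incidence, metric))
    dend <- run_stage("cluster", cluster_mirnas(sim, linkage))
    write_similarity(sim$similarity, p("similarity.tsv"))
    write_similarity(sim$shared, p("shared_counts.tsv"))
    write_dendrogram(dend, p("dendrogram.nwk"))
  }

  network <- NULL
  module_summary <- NULL
  if (!is.null(modules)) {
    module_set <- run_stage("network",
                            assign_modules(modules, integration$de_genes))
    module_summary <- run_stage("network",
                                module_direction_summary(module_set, sig_mrna))
    network <- run_stage("network",
      build_network(module_set, integration$filtered_pairs,
                    classify_direction(filter(mirna_de,
                      .data$feature_id %in% integration$de_mirnas$feature_id)),
                    sig_mrna,
                    keep_isolated_mirnas = keep_isolated_mirnas))
    readr::write_tsv(module_summary, p("module_summary.tsv"), progress = FALSE)
    write_network_sif(network, p("network.sif"))
    write_network_graphml(network, p("network.graphml"))
  }
  if (!is.null(ortholog_map)) {
    humanized <- run_stage("orthologs",
                           project_orthologs(sig_mrna, ortholog_map))
    readr::write_tsv(humanized, p("humanized_genes.tsv"), progress = FALSE)
  }

  report <- list(
    version = as.character(packageVersion("mirtarnet")),
    seed = seed,
    config = list(q_threshold = q_threshold, readjust = readjust,
                  metric = metric, linkage = linkage,
                  keep_isolated_mirnas = keep_isolated_mirnas),
    input_rows = n_input,
    significant_mrnas = length(integration$de_genes),
    significant_mirnas = nrow(integration$de_mirnas),
    mirna_up = sum(integration$de_mirnas$direction == "up"),
    mirna_down = sum(integration$de_mirnas$direction == "down"),
    predicted_union = length(integration$predicted_union),
    common = length(integration$common),
    filtered_pool = length(integration$filtered_pool),
    filtered_pairs = nrow(integration$filtered_pairs),
    multiplicity_histogram = setNames(as.list(histogram$n_genes),
                                      histogram$multiplicity),
    multi_targeted_genes = multi_targeted_count(histogram),
    module_summary = if (!is.null(module_summary)) {
      purrr::transpose(as.list(module_summary))
      } else NULL
  )
  if (isTRUE(include_timestamp)) {
    report$timestamp <- format(Sys.time(), tz = "UTC")
  }
  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  audit_run(report, out_dir)
  invisible(report)
}

# internal audit: every reported count must be re-derivable from the emitted
# artifacts
audit_run <- function(report, out_dir) {
  p <- function(f) file.path(out_dir, f)
  pairs <- readr::read_tsv(p("filtered_pairs.tsv"), col_types = "cccd",
                           progress = FALSE)
  stopifnot(
    nrow(pairs) == report$filtered_pairs,
    n_distinct(pairs$gene_id) == report$filtered_pool
  )
  hist <- read_histogram(p("histogram.tsv"))
  stopifnot(multi_targeted_count(hist) == report$multi_targeted_genes)
  venn <- readr::read_tsv(p("venn_counts.tsv"), col_types = "iii",
                          progress = FALSE)
  stopifnot(venn$common == report$common)
  invisible(TRUE)
}
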