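# Readers for the external tables the pipeline consumes. All tabular input is
# TSV with one header line; column names are resolved through an alias map so
# that DESeq2- and edgeR-flavoured headers both work unchanged.

#' Default column-name aliases for differential-expression tables
#'
#' Maps each canonical column of a DE result table to the header spellings
#' accepted on input. The first alias found in the file header wins; matching
#' is case-insensitive. Feature identifiers themselves are always compared
#' case-sensitively after whitespace trimming.
#'
#' @return Named list of character vectors, one per canonical column.
#' @export
#' @examples
#' names(de_column_aliases())
de_column_aliases <- function() {
  list(
    feature_id = c("feature_id", "id", "gene_id", "gene", "symbol",
                   "mirna_id", "mirna", "feature"),
    base_mean = c("base_mean", "basemean", "base.mean", "base mean"),
    log2_fold_change = c("log2_fold_change", "log2foldchange", "logfc",
                         "log2fc", "log2.fold.change"),
    p_value = c("p_value", "pvalue", "p", "p.value", "p-value"),
    q_value = c("q_value", "padj", "qvalue", "q", "fdr", "adj.p.val")
  )
}

# Resolve canonical -> actual header name; error names the missing column.
resolve_columns <- function(header, aliases, where) {
  low <- tolower(trimws(header))
  out <- character(0)
  for (canon in names(aliases)) {
    hit <- match(tolower(aliases[[canon]]), low)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) {
      stop_format(sprintf(
        "%s: required column '%s' not found (accepted names: %s)",
        where, canon, paste(aliases[[canon]], collapse = ", ")
      ))
    }
    out[[canon]] <- header[hit[1]]
  }
  out
}

read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file does not exist: %s", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

# Convert one character column to numeric; non-numeric entries raise a parse
# error naming the offending row(s).
parse_numeric_column <- function(x, column, where) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "%s: non-numeric value in column '%s' at row%s %s",
      where, column, if (length(bad) > 1) "s" else "",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  out
}

#' Read a differential-expression result table
#'
#' Reads a TSV of per-feature DE statistics (identifier, mean normalized
#' count, log2 fold change, p-value, BH-adjusted p-value) as produced by
#' count-based DE engines. Column headers are resolved via [de_column_aliases()].
#'
#' @param path Path to a tab-separated file with one header line.
#' @param feature_kind `"mRNA"` or `"miRNA"`; recorded as an attribute.
#' @param aliases Column alias map, see [de_column_aliases()].
#' @return A tibble with columns `feature_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `q_value`, in file row order.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
#'              "geneA\t100\t-1.5\t0.001\t0.01"), tsv)
#' read_de_table(tsv, "mRNA")
read_de_table <- function(path, feature_kind = c("mRNA", "miRNA"),
                          aliases = de_column_aliases()) {
  feature_kind <- match.arg(feature_kind)
  raw <- read_tsv_chr(path)
  where <- basename(path)
  cols <- resolve_columns(names(raw), aliases, where)

  if (nrow(raw) == 0) {
    out <- tibble(
      feature_id = character(0), base_mean = numeric(0),
      log2_fold_change = numeric(0), p_value = numeric(0), q_value = numeric(0)
    )
    attr(out, "feature_kind") <- feature_kind
    return(out)
  }

  out <- tibble(
    feature_id = trimws(raw[[cols[["feature_id"]]]]),
    base_mean = parse_numeric_column(raw[[cols[["base_mean"]]]], "base_mean", where),
    log2_fold_change = parse_numeric_column(
      raw[[cols[["log2_fold_change"]]]], "log2_fold_change", where),
    p_value = parse_numeric_column(raw[[cols[["p_value"]]]], "p_value", where),
    q_value = parse_numeric_column(raw[[cols[["q_value"]]]], "q_value", where)
  )
  validate_de_table(out, where)
  attr(out, "feature_kind") <- feature_kind
  out
}

validate_de_table <- function(tbl, where = "DE table") {
  if (any(is.na(tbl$feature_id) | tbl$feature_id == "")) {
    stop_validation(sprintf("%s: empty feature identifiers present", where))
  }
  dup <- unique(tbl$feature_id[duplicated(tbl$feature_id)])
  if (length(dup) > 0) {
    stop_validation(
      sprintf("%s: duplicated feature identifiers: %s", where,
              paste(dup, collapse = ", ")),
      duplicates = dup
    )
  }
  for (col in c("p_value", "q_value")) {
    x <- tbl[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop_validation(sprintf("%s: column '%s' outside [0, 1]", where, col))
    }
  }
  if (any(!is.na(tbl$base_mean) & tbl$base_mean < 0)) {
    stop_validation(sprintf("%s: negative base_mean values", where))
  }
  invisible(tbl)
}

#' Read a predicted miRNA-target table
#'
#' Reads miRNA-to-gene target predictions (e.g. a gene-level export of a
#' TargetScan-style database) and collapses duplicated (miRNA, gene) pairs.
#'
#' @param path Path to a TSV with at least a miRNA column and a gene column;
#'   an optional site-annotation column is carried through.
#' @return A tibble with columns `mirna_id`, `gene_id` and, when present,
#'   `site_annotation`; one row per unique (miRNA, gene) pair.
#' @export
read_target_predictions <- function(path) {
  raw <- read_tsv_chr(path)
  where <- basename(path)
  cols <- resolve_columns(names(raw), list(
    mirna_id = c("mirna_id", "mirna", "mir", "mirna id"),
    gene_id = c("gene_id", "gene", "target", "target_id", "gene id")
  ), where)
  site_col <- intersect(tolower(names(raw)),
                        c("site_annotation", "site", "site_type"))

  out <- tibble(
    mirna_id = trimws(raw[[cols[["mirna_id"]]]] %||% character(0)),
    gene_id = trimws(raw[[cols[["gene_id"]]]] %||% character(0))
  )
  if (length(site_col) > 0) {
    out$site_annotation <- raw[[match(site_col[1], tolower(names(raw)))]]
  }
  bad <- which(is.na(out$mirna_id) | out$mirna_id == "" |
                 is.na(out$gene_id) | out$gene_id == "")
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "%s: empty miRNA or gene field at row%s %s", where,
      if (length(bad) > 1) "s" else "", paste(head(bad, 10), collapse = ", ")
    ))
  }
  n_before <- nrow(out)
  out <- distinct(out, .data$mirna_id, .data$gene_id, .keep_all = TRUE)
  n_dup <- n_before - nrow(out)
  if (n_dup > 0) {
    inform(sprintf("%s: collapsed %d duplicated prediction pair%s",
                   where, n_dup, if (n_dup > 1) "s" else ""))
  }
  out
}

#' Read functional module definitions
#'
#' Reads a long-format table assigning genes to named functional modules
#' (e.g. "Cell cycle", "NAFLD"). A gene may appear in several modules;
#' overlap is resolved downstream by [assign_modules()].
#'
#' @param path Path to a TSV with a module-name column and a gene column.
#' @return A tibble with columns `module_name`, `gene_id`.
#' @export
read_modules <- function(path) {
  raw <- read_tsv_chr(path)
  where <- basename(path)
  cols <- resolve_columns(names(raw), list(
    module_name = c("module_name", "module", "module name"),
    gene_id = c("gene_id", "gene", "gene id")
  ), where)
  out <- tibble(
    module_name = trimws(raw[[cols[["module_name"]]]] %||% character(0)),
    gene_id = trimws(raw[[cols[["gene_id"]]]] %||% character(0))
  )
  bad <- which(is.na(out$module_name) | out$module_name == "" |
                 is.na(out$gene_id) | out$gene_id == "")
  if (length(bad) > 0) {
    stop_parse(sprintf("%s: empty module or gene field at rows %s", where,
                       paste(head(bad, 10), collapse = ", ")))
  }
  distinct(out)
}

#' Read an ortholog map
#'
#' Reads a two-column source-to-target gene identifier map (e.g. zebrafish to
#' human Ensembl orthologs). When one source id maps to several targets, the
#' first occurrence is kept and the conflict count is reported.
#'
#' @param path Path to a TSV with source and target identifier columns.
#' @return A tibble with columns `source_id`, `target_id`; `source_id` unique.
#' @export
read_ortholog_map <- function(path) {
  raw <- read_tsv_chr(path)
  where <- basename(path)
  cols <- resolve_columns(names(raw), list(
    source_id = c("source_id", "zebrafish_id", "zebrafish_gene", "source"),
    target_id = c("target_id", "human_id", "human_gene", "ortholog_id", "target")
  ), where)
  out <- tibble(
    source_id = trimws(raw[[cols[["source_id"]]]] %||% character(0)),
    target_id = trimws(raw[[cols[["target_id"]]]] %||% character(0))
  )
  bad <- which(is.na(out$source_id) | out$source_id == "" |
                 is.na(out$target_id) | out$target_id == "")
  if (length(bad) > 0) {
    stop_parse(sprintf("%s: empty identifier at rows %s", where,
                       paste(head(bad, 10), collapse = ", ")))
  }
  n_before <- nrow(out)
  out <- distinct(out, .data$source_id, .keep_all = TRUE)
  n_conflict <- n_before - nrow(out)
  if (n_conflict > 0) {
    inform(sprintf(
      "%s: %d source id%s mapped to multiple targets; kept first occurrence",
      where, n_conflict, if (n_conflict > 1) "s" else ""))
  }
  out
}
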