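# Published reference inputs shipped with the package.

#' Differentially expressed miRNAs from the BPA-exposed zebrafish liver
#'
#' The 15 significantly deregulated (q <= 0.1) hepatic miRNAs reported for
#' adult male zebrafish after chronic bisphenol A exposure, transcribed from
#' the published edgeR result table: 14 up-regulated and one down-regulated
#' (dre-miR-2189). Shipped as a TSV under `inst/extdata` and read through
#' [read_de_table()].
#'
#' @return A 15-row DE tibble (`feature_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `q_value`).
#' @export
#' @examples
#' bpa_mirna_de()
bpa_mirna_de <- function() {
  read_de_table(
    system.file("extdata", "bpa_liver_mirna_de.tsv", package = "mirtarnet",
                mustWork = TRUE),
    feature_kind = "miRNA"
  )
}
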