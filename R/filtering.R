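# Significance filtering: Benjamini-Hochberg adjustment, q-value thresholding
# and fold-change direction classification.

#' Benjamini-Hochberg adjustment
#'
#' Computes BH step-up adjusted p-values (q-values): on sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in input
#' order. This is the false-discovery-rate control used throughout the
#' pipeline (significance is called at `q <= 0.1` by default downstream).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; `NA` allowed and
#'   propagated.
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) {
    stop_domain("p_values must be numeric")
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_domain("p-values outside [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Filter a DE table to significant features
#'
#' Keeps records with `q_value <= q_threshold` (inclusive, so a q-value
#' exactly at the threshold survives). Input row order is preserved.
#'
#' @param records A DE tibble as returned by [read_de_table()].
#' @param q_threshold Significance cut on the adjusted p-value; default 0.1.
#' @param readjust If `TRUE`, recompute `q_value` from `p_value` with
#'   [bh_adjust()] before filtering; by default the q column shipped with the
#'   table (typically pre-adjusted by the DE engine) is used as-is.
#' @return The retained rows, a tibble.
#' @export
filter_significant <- function(records, q_threshold = 0.1, readjust = FALSE) {
  stopifnot(is.data.frame(records))
  if (isTRUE(readjust)) {
    records$q_value <- bh_adjust(records$p_value)
  }
  out <- filter(records, !is.na(.data$q_value), .data$q_value <= q_threshold)
  inform(sprintf("significance filter (q <= %g): retained %d of %d records",
                 q_threshold, nrow(out), nrow(records)))
  out
}

#' Classify fold-change direction
#'
#' Maps the sign of the log2 fold change to `"up"`, `"down"` or
#' `"unchanged"` (exactly zero). Genes and miRNAs classified `unchanged`
#' take no part in the anti-correlation filter.
#'
#' @param x A numeric vector of log2 fold changes, or a DE tibble (a
#'   `direction` column is appended).
#' @return A character vector, or the tibble with a `direction` column.
#' @export
#' @examples
#' classify_direction(c(2.6, -2.34, 0))
classify_direction <- function(x) {
  UseMethod("classify_direction")
}

#' @export
classify_direction.numeric <- function(x) {
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x > 0] <- "up"
  out[!is.na(x) & x < 0] <- "down"
  out[!is.na(x) & x == 0] <- "unchanged"
  out
}

#' @export
classify_direction.data.frame <- function(x) {
  x$direction <- classify_direction(x$log2_fold_change)
  x
}
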