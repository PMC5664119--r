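# Synthetic-data generators. simulate_dataset() emits DE tables and target
# prediction tables with planted, seeded structure (significant fractions,
# signed fold changes, anti-correlated targets, preferential-attachment
# target overlap) plus a truth object recording every planted assignment.
# build_histogram_fixture() deterministically realizes a requested
# target-multiplicity histogram. simulate_counts() emits negative-binomial
# count matrices for heatmap ordering.

#' Configuration for the synthetic miRNA/mRNA dataset generator
#'
#' Defaults emulate the shape of a liver miRNA-Seq + mRNA-Seq study at full
#' scale: a transcriptome-sized gene universe of which roughly 19% is
#' differentially expressed, a miRNome of a few hundred miRNAs of which 15
#' are differential (14 up, 1 down), and per-miRNA predicted target lists in
#' the low thousands whose reuse of already-targeted genes produces a
#' heavy-tailed multiplicity histogram.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_mirnas Number of miRNAs in the universe.
#' @param frac_de_genes Fraction of genes planted as differentially expressed.
#' @param n_de_mirnas_up,n_de_mirnas_down Planted up-/down-regulated miRNAs.
#' @param targets_per_mirna Predicted targets per miRNA: a single integer
#'   (fixed) or a length-2 integer range sampled uniformly.
#' @param overlap_weight Non-negative propensity to reuse already-targeted
#'   genes (preferential attachment). `0` forces disjoint target sets while
#'   untargeted genes remain.
#' @param anticorr_prob Probability that a planted DE target of an up-miRNA
#'   gets a negative log2 fold change (and vice versa for down-miRNAs).
#'   The default reflects that in real data roughly half of the significant
#'   predicted targets pass the opposite-sign filter.
#' @param effect_size_scale Mean magnitude of non-null log2 fold changes.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 32761, n_mirnas = 392,
                       frac_de_genes = 0.19,
                       n_de_mirnas_up = 14, n_de_mirnas_down = 1,
                       targets_per_mirna = c(800, 1600),
                       overlap_weight = 10,
                       anticorr_prob = 0.5,
                       effect_size_scale = 2,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    frac_de_genes = frac_de_genes,
    n_de_mirnas_up = as.integer(n_de_mirnas_up),
    n_de_mirnas_down = as.integer(n_de_mirnas_down),
    targets_per_mirna = as.integer(targets_per_mirna),
    overlap_weight = overlap_weight, anticorr_prob = anticorr_prob,
    effect_size_scale = effect_size_scale, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1 || cfg$n_mirnas < 1) {
    stop_config("n_genes and n_mirnas must be positive")
  }
  if (cfg$frac_de_genes <= 0 || cfg$frac_de_genes > 1) {
    stop_config("frac_de_genes must be in (0, 1]")
  }
  if (cfg$n_de_mirnas_up + cfg$n_de_mirnas_down > cfg$n_mirnas) {
    stop_config("n_de_mirnas_up + n_de_mirnas_down exceeds n_mirnas")
  }
  if (cfg$anticorr_prob < 0 || cfg$anticorr_prob > 1) {
    stop_config("anticorr_prob must be in [0, 1]")
  }
  if (cfg$overlap_weight < 0) stop_config("overlap_weight must be >= 0")
  if (!length(cfg$targets_per_mirna) %in% c(1, 2) ||
        any(cfg$targets_per_mirna < 1)) {
    stop_config("targets_per_mirna must be a positive integer or range")
  }
  if (max(cfg$targets_per_mirna) > cfg$n_genes) {
    stop_config("targets_per_mirna exceeds n_genes (infeasible)")
  }
  structure(cfg, class = "sim_config")
}

# Alternative p-values: Beta(0.05, 1) rescaled to (0, 1e-3]. The Beta shape
# keeps the null/alternative mixture analytically tractable; the rescaling
# guarantees every planted effect is recoverable at q <= 0.1, so BH recovers
# approximately frac_de_genes.
r_alt_p <- function(n) rbeta(n, 0.05, 1) * 1e-3

r_effect_magnitude <- function(n, scale) pmax(abs(rnorm(n, scale, 0.5)), 0.1)

zero_pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(4, nchar(n)), "d"), seq_len(n))
}

# Weighted target sampling with preferential attachment. `hits` counts how
# often each gene has been targeted so far; weight is 1 for untargeted genes
# and overlap_weight * hits for targeted ones.
sample_targets <- function(n_targets, hits, overlap_weight) {
  w <- ifelse(hits == 0, 1, overlap_weight * hits)
  pos <- which(w > 0)
  if (length(pos) >= n_targets) {
    idx <- sample(pos, n_targets, prob = w[pos])
  } else {
    # capacity exhausted under overlap_weight = 0: take every remaining
    # untargeted gene, fill the rest uniformly from targeted genes
    rest <- sample(setdiff(seq_along(hits), pos), n_targets - length(pos))
    idx <- c(pos, rest)
  }
  sort(idx)
}

#' Simulate a paired miRNA/mRNA differential-expression dataset
#'
#' Generates an mRNA DE table, a miRNA DE table, a target-prediction table
#' and a truth object under the supplied configuration. Null features draw
#' uniform p-values and small-noise fold changes; planted DE features draw
#' near-zero p-values and signed fold changes; q-values come from
#' [bh_adjust()]. Each DE gene targeted by at least one planted DE miRNA
#' takes its fold-change sign from its first targeting DE miRNA: with
#' probability `anticorr_prob` the sign opposes that miRNA's direction
#' (silencing-consistent), otherwise it matches it.
#'
#' @param config A [sim_config()] object.
#' @return A list with `mrna_de`, `mirna_de`, `predictions` (tibbles) and
#'   `truth` (planted assignments: `de_genes`, `de_mirnas`,
#'   `planted_targets`, `config`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  gene_ids <- zero_pad_ids("gene", config$n_genes)
  mirna_ids <- zero_pad_ids("mir-", config$n_mirnas)

  n_de_genes <- max(1L, round(config$frac_de_genes * config$n_genes))
  de_genes <- sort_cx(sample(gene_ids, n_de_genes))

  n_de_mir <- config$n_de_mirnas_up + config$n_de_mirnas_down
  de_mirna_ids <- sort_cx(sample(mirna_ids, n_de_mir))
  de_mirnas <- tibble(
    mirna_id = de_mirna_ids,
    direction = rep(c("up", "down"),
                    c(config$n_de_mirnas_up, config$n_de_mirnas_down))
  )

  # predictions: every miRNA gets a target list; overlap via preferential
  # attachment. DE miRNAs are drawn first so the gene-sign planting below can
  # reference the first DE miRNA that targeted each gene.
  hits <- integer(config$n_genes)
  mirna_order <- c(de_mirnas$mirna_id, setdiff(mirna_ids, de_mirnas$mirna_id))
  pred_list <- vector("list", config$n_mirnas)
  names(pred_list) <- mirna_order
  for (m in mirna_order) {
    t_m <- if (length(config$targets_per_mirna) == 1) {
      config$targets_per_mirna
    } else {
      sample(seq(config$targets_per_mirna[1], config$targets_per_mirna[2]), 1)
    }
    idx <- sample_targets(t_m, hits, config$overlap_weight)
    hits[idx] <- hits[idx] + 1L
    pred_list[[m]] <- idx
  }
  predictions <- tibble(
    mirna_id = rep(names(pred_list), lengths(pred_list)),
    gene_id = gene_ids[unlist(pred_list, use.names = FALSE)]
  )

  # gene fold-change signs: reference = first DE miRNA targeting the gene
  is_de_gene <- gene_ids %in% de_genes
  sign_vec <- ifelse(runif(config$n_genes) < 0.5, 1, -1)  # default random
  ref_mirna <- rep(NA_character_, config$n_genes)
  anticorr_draw <- runif(config$n_genes) < config$anticorr_prob
  for (k in seq_len(nrow(de_mirnas))) {
    m <- de_mirnas$mirna_id[k]
    dir_sign <- if (de_mirnas$direction[k] == "up") 1 else -1
    idx <- pred_list[[m]]
    fresh <- idx[is.na(ref_mirna[idx]) & is_de_gene[idx]]
    ref_mirna[fresh] <- m
    sign_vec[fresh] <- ifelse(anticorr_draw[fresh], -dir_sign, dir_sign)
  }

  # mRNA DE table
  p_gene <- runif(config$n_genes)
  p_gene[is_de_gene] <- r_alt_p(sum(is_de_gene))
  lfc_gene <- rnorm(config$n_genes, 0, 0.15)
  lfc_gene[is_de_gene] <- sign_vec[is_de_gene] *
    r_effect_magnitude(sum(is_de_gene), config$effect_size_scale)
  mrna_de <- tibble(
    feature_id = gene_ids,
    base_mean = round(rlnorm(config$n_genes, meanlog = 5, sdlog = 1.5), 2),
    log2_fold_change = lfc_gene,
    p_value = p_gene,
    q_value = bh_adjust(p_gene)
  )

  # miRNA DE table
  is_de_mir <- mirna_ids %in% de_mirnas$mirna_id
  p_mir <- runif(config$n_mirnas)
  p_mir[is_de_mir] <- r_alt_p(sum(is_de_mir))
  mir_sign <- rep(1, config$n_mirnas)
  mir_sign[match(de_mirnas$mirna_id, mirna_ids)] <-
    ifelse(de_mirnas$direction == "up", 1, -1)
  lfc_mir <- rnorm(config$n_mirnas, 0, 0.15)
  lfc_mir[is_de_mir] <- mir_sign[is_de_mir] *
    r_effect_magnitude(sum(is_de_mir), config$effect_size_scale)
  mirna_de <- tibble(
    feature_id = mirna_ids,
    base_mean = round(rlnorm(config$n_mirnas, meanlog = 4, sdlog = 1.5), 2),
    log2_fold_change = lfc_mir,
    p_value = p_mir,
    q_value = bh_adjust(p_mir)
  )

  planted_targets <- predictions |>
    filter(.data$mirna_id %in% de_mirnas$mirna_id) |>
    left_join(de_mirnas, by = "mirna_id") |>
    mutate(
      gene_is_de = .data$gene_id %in% de_genes,
      gene_sign = sign_vec[match(.data$gene_id, gene_ids)],
      reference_mirna = ref_mirna[match(.data$gene_id, gene_ids)],
      anticorrelated = .data$gene_is_de &
        ((.data$direction == "up" & .data$gene_sign < 0) |
           (.data$direction == "down" & .data$gene_sign > 0))
    )

  list(
    mrna_de = mrna_de,
    mirna_de = mirna_de,
    predictions = predictions[, c("mirna_id", "gene_id")],
    truth = list(
      de_genes = de_genes,
      de_mirnas = de_mirnas,
      planted_targets = planted_targets,
      config = config
    )
  )
}

#' Deterministic fixture realizing a target-multiplicity histogram
#'
#' Builds a prediction table and matching DE tables whose incidence matrix
#' reproduces the requested multiplicity histogram exactly: for each entry
#' `multiplicity -> n_genes`, that many genes are each assigned to that many
#' distinct miRNAs by a round-robin walk over the miRNA list. All miRNAs are
#' planted up-regulated and every fixture gene is significant with a negative
#' log2 fold change, so every pair survives the anti-correlation filter.
#'
#' @param histogram A tibble with columns `multiplicity`, `n_genes`, or a
#'   named vector (`names` = multiplicity).
#' @param n_mirnas Number of miRNAs to distribute targets over; must be at
#'   least the maximum multiplicity.
#' @param seed Seed for the (irrelevant-to-set-logic) fold-change magnitudes.
#' @return A list with `predictions`, `mrna_de`, `mirna_de`, `histogram`.
#' @export
#' @examples
#' fx <- build_histogram_fixture(tibble::tibble(multiplicity = 2, n_genes = 3),
#'                               n_mirnas = 4)
#' fx$predictions
build_histogram_fixture <- function(histogram, n_mirnas, seed = 1) {
  if (!is.data.frame(histogram)) {
    histogram <- tibble(multiplicity = as.integer(names(histogram)),
                        n_genes = as.integer(histogram))
  }
  histogram <- histogram |>
    mutate(multiplicity = as.integer(.data$multiplicity),
           n_genes = as.integer(.data$n_genes)) |>
    filter(.data$n_genes > 0) |>
    arrange(desc(.data$multiplicity))
  if (nrow(histogram) == 0) stop_config("empty histogram")
  if (max(histogram$multiplicity) > n_mirnas) {
    stop_config("histogram multiplicity exceeds n_mirnas")
  }
  set.seed(seed)

  n_genes <- sum(histogram$n_genes)
  gene_ids <- zero_pad_ids("fixgene", n_genes)
  mirna_ids <- zero_pad_ids("fixmir-", n_mirnas)

  mult_per_gene <- rep(histogram$multiplicity, histogram$n_genes)
  ptr <- 0L
  pairs <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    k <- mult_per_gene[g]
    idx <- ((ptr + seq_len(k) - 1L) %% n_mirnas) + 1L
    pairs[[g]] <- tibble(mirna_id = mirna_ids[idx], gene_id = gene_ids[g])
    ptr <- (ptr + k) %% n_mirnas
  }
  predictions <- bind_rows(pairs)

  mrna_de <- tibble(
    feature_id = gene_ids,
    base_mean = round(rlnorm(n_genes, 5, 1), 2),
    log2_fold_change = -r_effect_magnitude(n_genes, 2),
    p_value = 1e-6,
    q_value = 1e-4
  )
  mirna_de <- tibble(
    feature_id = mirna_ids,
    base_mean = round(rlnorm(n_mirnas, 4, 1), 2),
    log2_fold_change = r_effect_magnitude(n_mirnas, 2),
    p_value = 1e-6,
    q_value = 1e-4
  )
  list(predictions = predictions, mrna_de = mrna_de, mirna_de = mirna_de,
       histogram = arrange(histogram, .data$multiplicity))
}

#' Published target-multiplicity counts for the BPA-exposed liver study
#'
#' Returns the multiplicity histogram reported for genes targeted by more
#' than one differentially expressed miRNA in the BPA zebrafish liver
#' dataset (385 genes with multiplicity >= 2). With
#' `include_singletons = TRUE`, singleton genes are added so the total gene
#' count equals the 1491-gene filtered pool.
#'
#' @param include_singletons Add the `multiplicity = 1` row.
#' @return A tibble with columns `multiplicity`, `n_genes`.
#' @export
bpa_multiplicity_counts <- function(include_singletons = FALSE) {
  h <- tibble(
    multiplicity = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L),
    n_genes = c(196L, 96L, 59L, 21L, 5L, 5L, 2L, 1L)
  )
  if (include_singletons) {
    h <- bind_rows(tibble(multiplicity = 1L, n_genes = 1491L - sum(h$n_genes)), h)
  }
  h
}

#' Simulate a two-group count matrix
#'
#' Negative-binomial counts with group-dependent means for planted DE genes;
#' used as input for heatmap row/column ordering.
#'
#' @param n_genes Number of genes (rows).
#' @param n_samples_per_group Samples per group (columns: control then
#'   treated).
#' @param n_de Number of planted DE genes (the first `n_de` rows).
#' @param fold_change Multiplicative mean shift for planted genes in the
#'   treated group.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param seed Integer seed.
#' @return Integer matrix `n_genes` x `2 * n_samples_per_group` with a
#'   `de_genes` attribute naming the planted rows.
#' @export
simulate_counts <- function(n_genes, n_samples_per_group, n_de = 0,
                            fold_change = 2, dispersion = 0.1, seed = 1) {
  set.seed(seed)
  mu <- rlnorm(n_genes, meanlog = 5, sdlog = 1)
  size <- 1 / dispersion
  mu_mat <- matrix(mu, n_genes, 2 * n_samples_per_group)
  if (n_de > 0) {
    mu_mat[seq_len(n_de), n_samples_per_group + seq_len(n_samples_per_group)] <-
      mu[seq_len(n_de)] * fold_change
  }
  counts <- matrix(
    rnbinom(length(mu_mat), mu = as.vector(mu_mat), size = size),
    n_genes, 2 * n_samples_per_group
  )
  rownames(counts) <- zero_pad_ids("gene", n_genes)
  colnames(counts) <- c(paste0("ctrl_", seq_len(n_samples_per_group)),
                        paste0("trt_", seq_len(n_samples_per_group)))
  attr(counts, "de_genes") <- rownames(counts)[seq_len(n_de)]
  counts
}
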