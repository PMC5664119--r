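test_that("module assignment builds sorted derived sub-modules", {
  mods <- tibble::tibble(
    module_name = c("NAFLD", "Oxidative phosphorylation", "NAFLD",
                    "Cell cycle", "Apoptosis", "NAFLD"),
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3"))
  ms <- assign_modules(mods, c("g1", "g2", "g3"))
  a <- ms$assignment
  expect_equal(a$module[a$gene_id == "g2"], "NAFLD")
  expect_equal(a$module[a$gene_id == "g1"],
               "NAFLD+Oxidative phosphorylation")
  expect_equal(a$module[a$gene_id == "g3"],
               "Apoptosis+Cell cycle+NAFLD")
  expect_setequal(ms$derived_submodules,
                  c("NAFLD+Oxidative phosphorylation",
                    "Apoptosis+Cell cycle+NAFLD"))
  # genes not significant are not assigned
  expect_false("g4" %in% assign_modules(
    tibble::tibble(module_name = "M", gene_id = "g4"),
    c("g1"))$assignment$gene_id)
})

test_that("module direction summary partitions by fold-change sign", {
  mods <- tibble::tibble(module_name = rep("M", 3),
                         gene_id = c("g1", "g2", "g3"))
  genes <- de_tbl(c("g1", "g2", "g3"), c(-1, -2, 0.5))
  ms <- assign_modules(mods, genes$feature_id)
  s <- module_direction_summary(ms, genes)
  expect_equal(s$n_up, 1L)
  expect_equal(s$n_down, 2L)

  # base module with no significant genes: zero counts plus warning
  mods2 <- tibble::tibble(module_name = c("M", "Empty"),
                          gene_id = c("g1", "gX"))
  ms2 <- assign_modules(mods2, genes$feature_id)
  expect_warning(s2 <- module_direction_summary(ms2, genes), "Empty")
  expect_equal(s2$n_genes[s2$module == "Empty"], 0L)
})

test_that("a planted all-down module summarizes with zero up-regulated genes", {
  sim <- simulate_dataset(sim_config(
    n_genes = 300, n_mirnas = 8, frac_de_genes = 0.4, n_de_mirnas_up = 2,
    n_de_mirnas_down = 0, targets_per_mirna = 20, anticorr_prob = 1,
    seed = 29))
  it <- suppressMessages(integrate_targets(sim$mrna_de, sim$mirna_de,
                                           sim$predictions))
  # all filtered-pool genes are down by construction: use them as a module
  mods <- tibble::tibble(module_name = "planted down",
                         gene_id = it$filtered_pool)
  ms <- assign_modules(mods, it$de_genes)
  s <- module_direction_summary(
    ms, suppressMessages(filter_significant(sim$mrna_de)))
  expect_equal(s$n_up, 0L)
  expect_equal(s$n_genes, length(it$filtered_pool))
})

test_that("minimal network has three nodes and two typed edges", {
  ms <- assign_modules(tibble::tibble(module_name = "M", gene_id = "g1"), "g1")
  pairs <- tibble::tibble(mirna_id = "m1", gene_id = "g1",
                          mirna_direction = "up", gene_log2fc = -1)
  net <- build_network(ms, pairs, de_tbl("m1", 2), de_tbl("g1", -1))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$relation, c("targets", "member_of"))
  expect_true(net$nodes$targeted[net$nodes$id == "g1"])
})

test_that("modules without targeted genes stay in the network untargeted", {
  mods <- tibble::tibble(module_name = c("A", "B"), gene_id = c("g1", "g2"))
  genes <- de_tbl(c("g1", "g2"), c(-1, -1))
  ms <- assign_modules(mods, genes$feature_id)
  pairs <- tibble::tibble(mirna_id = "m1", gene_id = "g1",
                          mirna_direction = "up", gene_log2fc = -1)
  net <- build_network(ms, pairs, de_tbl("m1", 2), genes)
  expect_true("B" %in% net$nodes$id)
  expect_false(net$nodes$targeted[net$nodes$id == "g2"])
  # isolated miRNAs are dropped by default but kept on request
  net2 <- build_network(ms, pairs, de_tbl(c("m1", "m2"), c(2, 1)), genes)
  expect_false("m2" %in% net2$nodes$id)
  net3 <- build_network(ms, pairs, de_tbl(c("m1", "m2"), c(2, 1)), genes,
                        keep_isolated_mirnas = TRUE)
  expect_true("m2" %in% net3$nodes$id)
})

test_that("network counts match exhaustive enumeration on random inputs", {
  set.seed(47)
  for (i in 1:10) {
    genes <- de_tbl(sprintf("g%02d", 1:30),
                    sample(c(-1, 1), 30, TRUE) * runif(30, 0.5, 3))
    mirnas <- de_tbl(sprintf("m%d", 1:5),
                     sample(c(-1, 1), 5, TRUE) * runif(5, 0.5, 3))
    preds <- tibble::tibble(
      mirna_id = sample(mirnas$feature_id, 60, TRUE),
      gene_id = sample(genes$feature_id, 60, TRUE)) |> dplyr::distinct()
    pairs <- anticorrelation_filter(genes$feature_id, genes, mirnas, preds)
    mods <- tibble::tibble(
      module_name = sample(c("M1", "M2", "M3"), 20, TRUE),
      gene_id = sample(genes$feature_id, 20, TRUE)) |> dplyr::distinct()
    ms <- assign_modules(mods, genes$feature_id)
    net <- build_network(ms, pairs, mirnas, genes)
    gl <- glance(net)
    oracle <- network_counts_oracle(ms$assignment, pairs, mirnas)
    expect_equal(gl$n_targets, oracle$n_targets)
    expect_equal(gl$n_member_of, oracle$n_member_of)
    expect_equal(gl$n_mirnas, oracle$n_mirnas)
    expect_equal(gl$n_genes, oracle$n_genes)
    expect_equal(gl$n_modules, oracle$n_modules)

    # sign-consistency audit over the whole graph
    dirs <- setNames(classify_direction(mirnas$log2_fold_change),
                     mirnas$feature_id)
    lfc <- setNames(genes$log2_fold_change, genes$feature_id)
    tedges <- net$edges[net$edges$relation == "targets", ]
    expect_true(all(
      (dirs[tedges$from] == "up" & lfc[tedges$to] < 0) |
        (dirs[tedges$from] == "down" & lfc[tedges$to] > 0)))
    # every gene node has exactly one member_of edge
    medges <- net$edges[net$edges$relation == "member_of", ]
    gene_nodes <- net$nodes$id[net$nodes$node_type == "gene"]
    expect_setequal(medges$from, gene_nodes)
    expect_equal(anyDuplicated(medges$from), 0)
  }
})

test_that("ortholog projection joins and counts unmapped genes", {
  genes <- de_tbl(c("gA", "gB"), c(1, -1))
  om <- tibble::tibble(source_id = "gA", target_id = "HA")
  out <- suppressMessages(project_orthologs(genes, om))
  expect_equal(out$ortholog_id, c("HA", NA))
  expect_equal(attr(out, "n_unmapped"), 1)

  all_un <- suppressMessages(project_orthologs(
    genes, tibble::tibble(source_id = character(0),
                          target_id = character(0))))
  expect_true(all(is.na(all_un$ortholog_id)))

  # constructed 70% coverage maps back exactly
  set.seed(5)
  ids <- sprintf("g%03d", 1:200)
  genes2 <- de_tbl(ids, rnorm(200))
  mapped <- sample(ids, 140)
  om2 <- tibble::tibble(source_id = mapped, target_id = toupper(mapped))
  out2 <- suppressMessages(project_orthologs(genes2, om2))
  expect_equal(attr(out2, "n_mapped"), 140)
  expect_equal(attr(out2, "n_mapped") / nrow(out2), 0.7)
})
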