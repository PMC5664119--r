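pairs_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(mirna_id = m[, 1], gene_id = m[, 2])
}

test_that("incidence matrix has deterministic ordering and binary cells", {
  pairs <- pairs_tbl("m1", "g1", "m1", "g2", "m2", "g2")
  mat <- build_incidence(pairs)
  expect_equal(rownames(mat), c("m1", "m2"))
  expect_equal(colnames(mat), c("g1", "g2"))
  expect_equal(unname(colSums(mat)), c(1, 2))
  expect_true(all(mat %in% 0:1))

  expect_warning(empty <- build_incidence(pairs[0, ]), "zero gene columns")
  expect_equal(ncol(empty), 0)
})

test_that("multiplicity histogram matches published fixture and identities", {
  fx <- build_histogram_fixture(bpa_multiplicity_counts(), n_mirnas = 15)
  it <- suppressMessages(integrate_targets(fx$mrna_de, fx$mirna_de,
                                           fx$predictions))
  mat <- build_incidence(it$filtered_pairs,
                         mirna_order = it$de_mirnas$feature_id)
  expect_equal(nrow(mat), 15)
  h <- multiplicity_histogram(mat)
  expect_equal(h[, c("multiplicity", "n_genes")],
               bpa_multiplicity_counts(), ignore_attr = TRUE)
  expect_equal(multi_targeted_count(h), 385)
  # permuting miRNA labels leaves the histogram invariant
  perm <- mat[sample(nrow(mat)), ]
  expect_equal(multiplicity_histogram(perm), h, ignore_attr = TRUE)

  expect_equal(multiplicity_histogram(diag(3))$n_genes, 3)
  expect_equal(multi_targeted_count(multiplicity_histogram(diag(3))), 0)
  all1 <- matrix(1L, 4, 6, dimnames = list(paste0("m", 1:4), paste0("g", 1:6)))
  h46 <- multiplicity_histogram(all1)
  expect_equal(h46$multiplicity, 4L)
  expect_equal(h46$n_genes, 6L)
  expect_equal(multi_targeted_count(h46), 6)
})

test_that("histogram total mass equals the incidence cell sum", {
  set.seed(31)
  for (i in 1:10) {
    mat <- random_incidence(sample(3:8, 1), sample(10:40, 1), runif(1, 0.1, 0.6))
    h <- multiplicity_histogram(mat)
    expect_equal(sum(h$multiplicity * h$n_genes), sum(mat))
  }
})

test_that("Jaccard similarity counts shared targets", {
  mat <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))
  colnames(mat) <- paste0("g", 1:4)
  s <- pairwise_similarity(mat)
  expect_equal(s$similarity["a", "b"], 0.5)   # |{g2,g3}| / |{g1..g4}|
  expect_equal(s$shared["a", "b"], 2L)

  same <- rbind(a = c(1, 1), b = c(1, 1)); colnames(same) <- c("g1", "g2")
  expect_equal(pairwise_similarity(same)$similarity["a", "b"], 1)

  disj <- rbind(a = c(1, 0), b = c(0, 1)); colnames(disj) <- c("g1", "g2")
  sd <- pairwise_similarity(disj)
  expect_equal(sd$similarity["a", "b"], 0)
  expect_equal(sd$distance["a", "b"], 1)

  expect_error(pairwise_similarity(mat[1, , drop = FALSE]),
               class = "mirtarnet_degenerate_error")
  both_empty <- rbind(a = c(0, 0), b = c(0, 0)); colnames(both_empty) <- c("g1", "g2")
  expect_warning(se <- pairwise_similarity(both_empty), "empty")
  expect_equal(se$similarity["a", "b"], 0)
})

test_that("similarity agrees with the direct set-counting oracle", {
  set.seed(41)
  for (i in 1:10) {
    mat <- random_incidence(5, 30, 0.3)
    s <- pairwise_similarity(mat)
    for (a in 1:4) for (b in (a + 1):5) {
      expect_equal(s$similarity[a, b],
                   jaccard_oracle(which(mat[a, ] == 1), which(mat[b, ] == 1)))
    }
  }
})

test_that("Jaccard distance satisfies the triangle inequality", {
  set.seed(43)
  for (i in 1:20) {
    mat <- random_incidence(3, 25, runif(1, 0.2, 0.7))
    d <- pairwise_similarity(mat)$distance
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-12)
  }
})

test_that("clustering merges identical target sets first, disjoint miRNAs last", {
  mat <- rbind(mA = c(1, 1, 0, 0), mB = c(1, 1, 0, 0), mC = c(0, 1, 1, 1))
  colnames(mat) <- paste0("g", 1:4)
  d <- cluster_mirnas(pairwise_similarity(mat))
  expect_equal(d$height[1], 0)
  expect_setequal(d$merge[1, ], c(-1, -2))  # the identical pair

  for (linkage in c("average", "complete")) {
    mat2 <- rbind(m1 = c(1, 1, 0, 0, 0), m2 = c(1, 1, 1, 0, 0),
                  m3 = c(0, 1, 1, 0, 0), lone = c(0, 0, 0, 1, 1))
    colnames(mat2) <- paste0("g", 1:5)
    d2 <- cluster_mirnas(pairwise_similarity(mat2), linkage)
    last <- d2$merge[nrow(d2$merge), ]
    expect_true(-4 %in% last)             # the disjoint miRNA joins last
    expect_equal(d2$height[length(d2$height)], 1)
  }

  expect_error(cluster_mirnas(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               class = "mirtarnet_validation_error")
})

test_that("agglomeration matches stats::hclust on tie-free cases", {
  set.seed(11)
  for (i in 1:6) {
    # jitter cells so inter-set distances are essentially tie-free
    mat <- random_incidence(6, 40, 0.4)
    s <- pairwise_similarity(mat)
    # perturb to remove exact ties while keeping symmetry
    pert <- matrix(runif(36, 0, 1e-6), 6, 6)
    pert <- (pert + t(pert)) / 2; diag(pert) <- 0
    sim <- s$similarity - pert
    diag(sim) <- 1
    rownames(sim) <- colnames(sim) <- rownames(mat)
    for (linkage in c("average", "complete")) {
      mine <- as.hclust(cluster_mirnas(sim, linkage))
      ref <- hclust(as.dist(1 - sim), method = linkage)
      expect_equal(cophenetic(mine), cophenetic(ref), tolerance = 1e-10)
    }
  }
})

test_that("ward linkage reproduces hclust ward.D2 on tie-free distances", {
  set.seed(19)
  d <- matrix(runif(49, 0.2, 1), 7, 7)
  d <- (d + t(d)) / 2; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("m", 1:7)
  mine <- as.hclust(cluster_mirnas(1 - d, "ward"))
  ref <- hclust(as.dist(d), method = "ward.D2")
  expect_equal(cophenetic(mine), cophenetic(ref), tolerance = 1e-10)
})

test_that("heatmap ordering clusters by Euclidean distance under Ward", {
  # identical rows merge at height zero
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  ord <- heatmap_order(x, normalize = "none")
  expect_equal(ord$row_tree$height[1], 0)
  expect_setequal(ord$row_tree$merge[1, ], c(-1, -2))

  # hand-computed distances: d12 = 3, d13 = 4, d23 = 5 -> rows 1,2 merge first
  y <- rbind(r1 = c(0, 0), r2 = c(0, 3), r3 = c(4, 0))
  ordy <- heatmap_order(y, normalize = "none")
  expect_setequal(ordy$row_tree$merge[1, ], c(-1, -2))

  # deterministic rerun
  expect_identical(heatmap_order(y, normalize = "none")$row_order,
                   ordy$row_order)
  expect_warning(heatmap_order(matrix(1, 3, 3)), "constant")
  expect_error(heatmap_order(matrix(c(1, Inf, 2, 3), 2, 2)),
               class = "mirtarnet_validation_error")
})

test_that("dendrogram tidier reports one merge per step", {
  mat <- random_incidence(5, 20, 0.4)
  set.seed(2)
  d <- cluster_mirnas(pairwise_similarity(mat))
  td <- tidy(d)
  expect_equal(nrow(td), 4)
  expect_equal(td$height, d$height)
})
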