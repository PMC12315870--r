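test_that("QC filtering applies the two-stage rule and is idempotent", {
  # thresholds (0, 0, 1) are the identity
  tc <- toy_counts()
  expect_identical(qc_filter(tc, 0, 0, 1)$values, tc$values)

  # cell 'a' detects 2 genes, cell 'b' 2, cell 'c' 2; make 'a' express 1 gene
  m <- matrix(c(5, 0, 0,
                1, 3, 0,
                0, 4, 5), nrow = 3, byrow = TRUE)
  cm <- count_matrix(m, cell_ids = c("a", "b", "c"),
                     gene_ids = c("g1", "g2", "g3"))
  f <- qc_filter(cm, min_genes_per_cell = 2, min_cells_per_gene = 0,
                 max_mito_fraction = 1)
  expect_identical(f$cell_ids, c("b", "c"))

  # gene expressed only in a removed cell is dropped by the second stage
  m2 <- matrix(c(9, 0, 0,
                 0, 3, 1,
                 0, 4, 5), nrow = 3, byrow = TRUE)
  cm2 <- count_matrix(m2, cell_ids = c("a", "b", "c"),
                      gene_ids = c("g1", "g2", "g3"))
  f2 <- qc_filter(cm2, min_genes_per_cell = 2, min_cells_per_gene = 1,
                  max_mito_fraction = 1)
  expect_identical(f2$gene_ids, c("g2", "g3"))  # manual two-stage evaluation

  # mitochondrial fraction filter
  m3 <- matrix(c(1, 9,
                 9, 1), nrow = 2, byrow = TRUE)
  cm3 <- count_matrix(m3, cell_ids = c("hi", "lo"),
                      gene_ids = c("g1", "MT-1"))
  f3 <- qc_filter(cm3, 0, 0, max_mito_fraction = 0.5)
  expect_identical(f3$cell_ids, "lo")

  # idempotence on a simulated matrix
  sim <- small_sim(mito_gene_fraction = 0.05)
  once <- qc_filter(sim$counts, 50, 3, 0.2)
  twice <- qc_filter(once, 50, 3, 0.2)
  expect_identical(once$values, twice$values)

  expect_error(qc_filter(cm3, 10, 0, 1), "empty matrix after QC")
})

test_that("log normalization matches the closed form and round-trips", {
  cm <- count_matrix(matrix(c(2, 0, 2), 1), cell_ids = "c1",
                     gene_ids = c("g1", "g2", "g3"))
  nm <- normalize_log(cm, target_sum = 4)
  expect_equal(as.numeric(nm$values), c(log(3), 0, log(3)))

  sim <- small_sim(n_cells = 100, n_genes = 80)
  nm2 <- normalize_log(sim$counts)
  # all-zero gene stays all-zero
  zg <- which(colSums(sim$counts$values) == 0)
  if (length(zg)) expect_true(all(nm2$values[, zg] == 0))
  # round trip to counts at 1e-9 relative error
  rec <- expm1(nm2$values) * (nm2$cell_totals / nm2$target_sum)
  expect_equal(rec, sim$counts$values, tolerance = 1e-9,
               ignore_attr = TRUE)

  bad <- count_matrix(matrix(c(1, 0, 0, 0), 2), cell_ids = c("ok", "empty"))
  expect_error(normalize_log(bad), "empty")
})

test_that("highly variable gene selection is deterministic and signal-driven", {
  sim <- small_sim(n_cells = 2000, n_genes = 300, marker_log2fc = 3,
                   seed = 31)
  nm <- normalize_log(sim$counts)
  # n = all genes returns every gene exactly once
  all_g <- select_hvg(nm, n = 300)
  expect_setequal(all_g, 1:300)
  expect_identical(all_g, select_hvg(nm, n = 300))
  expect_error(select_hvg(nm, n = 301), "exceeds")

  # a constant gene never precedes a gene with positive variance
  v <- nm$values
  v[, 5] <- 0.7                      # constant expression
  nm_const <- nm; nm_const$values <- v
  ord <- select_hvg(nm_const, n = 300)
  n_positive <- sum(apply(v, 2, var) > 0)
  expect_gt(match(5, ord), n_positive)

  # true markers are enriched among the selected half (one-sided)
  sel <- select_hvg(nm, n = 60)
  mk <- unlist(sim$truth$marker_genes_of_type)
  tab <- table(marker = 1:300 %in% mk, selected = 1:300 %in% sel)
  expect_lt(fisher.test(tab, alternative = "greater")$p.value, 0.01)
})

test_that("PCA embedding matches a closed-form eigendecomposition", {
  # 4-point toy in 2-D; component 1 by hand from the 2x2 covariance
  pts <- matrix(c(0, 0,
                  2, 1,
                  4, 2,
                  6, 3), ncol = 2, byrow = TRUE)
  nm <- structure(list(values = pts, target_sum = NA, cell_totals = rep(1, 4),
                       cell_ids = paste0("c", 1:4), gene_ids = c("x", "y")),
                  class = "norm_matrix")
  emb <- suppressWarnings(pca_embed(nm, 1:2, n_components = 2))
  # points are collinear along (2,1)/sqrt(5): scores are signed distances
  centered <- sweep(pts, 2, colMeans(pts))
  expected_pc1 <- centered %*% (c(2, 1) / sqrt(5))
  expect_equal(as.numeric(emb[, 1]), as.numeric(expected_pc1),
               tolerance = 1e-8)

  # duplicate cells map to identical embedding rows
  sim <- small_sim(n_cells = 60, n_genes = 50, marker_genes_per_type = 20)
  nm2 <- normalize_log(sim$counts)
  nm2$values[2, ] <- nm2$values[1, ]
  e2 <- suppressWarnings(pca_embed(nm2, 1:50, n_components = 10))
  expect_equal(e2[1, ], e2[2, ], tolerance = 1e-10, ignore_attr = TRUE)

  # full-rank reconstruction of the centered input
  small <- normalize_log(small_sim(n_cells = 30, n_genes = 20, marker_genes_per_type = 8)$counts)
  x <- small$values - rep(colMeans(small$values), each = 30)
  sv <- svd(x)
  emb_full <- suppressWarnings(pca_embed(small, 1:20, n_components = 20))
  # scores have the same column norms as the exact SVD scores
  expect_equal(sqrt(colSums(emb_full^2))[seq_along(sv$d)], sv$d,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("k-NN graph is exact with deterministic tie-breaking", {
  # collinear toy: 0, 1, 3 -> nearest neighbors 2, 1, 2
  emb <- matrix(c(0, 1, 3), ncol = 1)
  rownames(emb) <- c("a", "b", "c")
  g <- knn_graph(emb, k = 1)
  expect_equal(as.integer(g$idx), c(2L, 1L, 2L))

  # symmetric square: diagonal tie resolved to the lower cell index
  sq <- matrix(c(0, 0,
                 1, 0,
                 0, 1,
                 1, 1), ncol = 2, byrow = TRUE)
  g2 <- knn_graph(sq, k = 3)
  # for cell 1, neighbors 2 and 3 tie at distance 1 -> 2 first
  expect_equal(g2$idx[1, ], c(2L, 3L, 4L))

  # brute-force agreement on a random 200-point set
  set.seed(77)
  pts <- matrix(rnorm(200 * 5), 200)
  g3 <- knn_graph(pts, k = 15)
  D <- as.matrix(dist(pts))
  for (i in c(1, 50, 111, 200)) {
    ord <- setdiff(order(D[i, ], seq_len(200)), i)[1:15]
    expect_equal(g3$idx[i, ], as.integer(ord))
  }
  expect_error(knn_graph(sq, k = 4), "smaller")
})

test_that("Leiden clustering separates simulated types and is deterministic", {
  sim <- small_sim(n_cells = 500, n_genes = 300, n_cell_types = 2,
                   marker_genes_per_type = 50, marker_log2fc = 4, seed = 17)
  pp0 <- preprocess(sim$counts, n_hvg = 300, seed = 1)
  truth <- sim$truth$cell_type_of_cell
  for (s in 1:5) {
    cl <- leiden_cluster(pp0$graph, seed = s)
    expect_equal(length(unique(unclass(cl))), 2)
    expect_equal(adjusted_rand_index(cl, truth), 1)
  }
  # identical graph + seed -> identical labels
  expect_identical(unclass(leiden_cluster(pp0$graph, seed = 3)),
                   unclass(leiden_cluster(pp0$graph, seed = 3)))
  # labels ordered by descending size
  sizes <- as.integer(table(unclass(leiden_cluster(pp0$graph, seed = 3))))
  expect_true(all(diff(sizes) <= 0))

  # a single clique collapses to one cluster at resolution 1
  clique <- knn_graph(matrix(rnorm(8), 8, 1) * 1e-9 +
                        matrix(0, 8, 1), k = 7)
  cl1 <- leiden_cluster(clique, seed = 1)
  expect_equal(length(unique(unclass(cl1))), 1)
})

test_that("the full uncorrected pipeline is deterministic", {
  sim <- small_sim(n_cells = 150, n_genes = 100)
  a <- preprocess(sim$counts, n_hvg = 100, seed = 9)
  b <- preprocess(sim$counts, n_hvg = 100, seed = 9)
  expect_identical(a$embedding, b$embedding)
  expect_identical(unclass(a$clustering), unclass(b$clustering))
})
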