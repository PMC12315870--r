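test_that("simulation is reproducible and respects the declared structure", {
  cfg <- sim_config(n_cells = 150, n_genes = 120, n_cell_types = 3,
                    marker_genes_per_type = 10, seed = 42,
                    mito_gene_fraction = 0.1)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$truth, b$truth)

  expect_equal(dim(a$counts$values), c(150, 120))
  expect_true(all(a$counts$values >= 0))
  expect_true(all(a$counts$values == floor(a$counts$values)))
  expect_equal(sum(grepl("^MT-", a$counts$gene_ids)), 12)  # floor(0.1*120)
  # marker sets disjoint, one type per cell
  mk <- a$truth$marker_genes_of_type
  expect_equal(length(unlist(mk)), length(unique(unlist(mk))))
  expect_equal(length(a$truth$cell_type_of_cell), 150)
  expect_equal(sort(unique(a$truth$cell_type_of_cell)),
               c("type1", "type2", "type3"))
})

test_that("degenerate configurations behave as no-ops", {
  # one type, no markers: no structure requested
  one <- simulate_counts(sim_config(n_cells = 50, n_genes = 40,
                                    n_cell_types = 1,
                                    marker_genes_per_type = 0, seed = 3))
  expect_equal(unique(one$truth$cell_type_of_cell), "type1")
  expect_equal(lengths(one$truth$marker_genes_of_type), c(type1 = 0L))

  # fold change 1 (log2fc = 0): "markers" are statistically indistinguishable
  flat <- simulate_counts(sim_config(n_cells = 2000, n_genes = 100,
                                     n_cell_types = 2,
                                     marker_genes_per_type = 10,
                                     marker_log2fc = 0, seed = 7))
  type <- flat$truth$cell_type_of_cell
  mk1 <- flat$truth$marker_genes_of_type$type1
  inside <- rowMeans(flat$counts$values[type == "type1", mk1, drop = FALSE])
  outside <- rowMeans(flat$counts$values[type != "type1", mk1, drop = FALSE])
  expect_gt(t.test(inside, outside)$p.value, 0.01)
})

test_that("marker fold change is realized at the configured magnitude", {
  # interval frozen from a 99% Monte-Carlo envelope of the generative model
  # (100 oracle runs at these parameters, genes with out-of-type mean >= 1)
  sim <- simulate_counts(sim_config(n_cells = 1000, n_genes = 500,
                                    n_cell_types = 3,
                                    marker_genes_per_type = 50,
                                    marker_log2fc = 2, base_mean = 1,
                                    seed = 11))
  type <- sim$truth$cell_type_of_cell
  for (t in names(sim$truth$marker_genes_of_type)) {
    for (g in sim$truth$marker_genes_of_type[[t]]) {
      out_mean <- mean(sim$counts$values[type != t, g])
      if (out_mean < 1) next
      ratio <- mean(sim$counts$values[type == t, g]) / out_mean
      expect_gte(ratio, 3.0)
      expect_lte(ratio, 5.3)
    }
  }
})

test_that("batch-effect injection thins only the designated block", {
  sim <- small_sim()
  counts <- sim$counts
  n <- nrow(counts$values)
  split <- random_split(n, seed = 2)
  genes <- 1:40

  # factor 1 is the identity
  same <- inject_batch_effect(counts, split, genes, factor = 1, seed = 9)
  expect_identical(same$values, counts$values)

  thin <- inject_batch_effect(counts, split, genes, factor = 0.5, seed = 9,
                              batch = "B")
  in_b <- split == "B"
  # untouched partitions are bit-identical
  expect_identical(thin$values[!in_b, ], counts$values[!in_b, ])
  expect_identical(thin$values[, -genes], counts$values[, -genes])
  # binomial-sum oracle: |observed - 0.5 T| < 4 sqrt(0.25 T)
  T_in <- sum(counts$values[in_b, genes])
  T_out <- sum(thin$values[in_b, genes])
  expect_lt(abs(T_out - 0.5 * T_in), 4 * sqrt(0.25 * T_in))
  # never increases a count
  expect_true(all(thin$values <= counts$values))

  expect_error(inject_batch_effect(counts, split, c(1, 10^6), 0.5),
               "unknown gene")
  expect_error(inject_batch_effect(counts, split, genes, 1.5), "factor")
  expect_error(inject_batch_effect(counts, split, genes, 0), "factor")
})

test_that("repeated thinning composes multiplicatively in distribution", {
  sim <- small_sim(n_cells = 200, n_genes = 100)
  counts <- sim$counts
  split <- random_split(200, seed = 4)
  genes <- 1:30
  in_b <- split == "B"
  T0 <- sum(counts$values[in_b, genes])
  tot2 <- vapply(1:50, function(s) {
    a <- inject_batch_effect(counts, split, genes, 0.8, seed = s)
    b <- inject_batch_effect(a, split, genes, 0.5, seed = s + 1000)
    sum(b$values[in_b, genes])
  }, 0)
  # mean of 50 composed runs vs single thinning at 0.4: 4 sigma of the mean
  expect_lt(abs(mean(tot2) - 0.4 * T0), 4 * sqrt(0.4 * 0.6 * T0 / 50))
})

test_that("exact-mode injection is deterministic multiplication", {
  sim <- small_sim(n_cells = 100, n_genes = 80)
  split <- random_split(100, seed = 1)
  ex <- inject_batch_effect(sim$counts, split, 1:10, 0.5, mode = "exact")
  in_b <- split == "B"
  expect_equal(ex$values[in_b, 1:10], sim$counts$values[in_b, 1:10] * 0.5)
  eff <- attr(ex, "injected_effect")
  expect_equal(eff$factor, 0.5)
  expect_equal(eff$mode, "exact")
})

test_that("perturbation targets recover true markers", {
  sim <- small_sim(n_cells = 2000, n_genes = 400, n_cell_types = 2,
                   marker_genes_per_type = 100, marker_log2fc = 3, seed = 21)
  pp <- preprocess(sim$counts, n_hvg = 400, seed = 1)
  truth_mk <- sim$truth$marker_genes_of_type
  # locate the cluster matching type1 by its first marker gene
  cl1 <- identify_cluster_by_marker(pp$norm, pp$clustering,
                                    sim$counts$gene_ids[truth_mk$type1[1]])
  sel <- select_perturbation_targets(sim$counts, pp$clustering, cl1,
                                     n_genes = 100)
  expect_length(sel, 100)
  expect_gte(length(intersect(sel, truth_mk$type1)), 90)
  # determinism and the n_genes = 0 edge
  expect_identical(sel, select_perturbation_targets(sim$counts, pp$clustering,
                                                    cl1, n_genes = 100))
  expect_identical(select_perturbation_targets(sim$counts, pp$clustering,
                                               cl1, n_genes = 0), integer(0))
})

test_that("batch downsampling halves totals and errors on bad input", {
  sim <- small_sim(n_cells = 300, n_genes = 200)
  split <- random_split(300, seed = 8)
  same <- downsample_batch(sim$counts, split, "A", p = 1)
  expect_identical(same$values, sim$counts$values)

  half <- downsample_batch(sim$counts, split, "A", p = 0.5, seed = 13)
  in_a <- split == "A"
  T_in <- sum(sim$counts$values[in_a, ])
  expect_lt(abs(sum(half$values[in_a, ]) - 0.5 * T_in), 4 * sqrt(0.25 * T_in))
  expect_identical(half$values[!in_a, ], sim$counts$values[!in_a, ])
  # per-cell totals roughly halved
  cells <- which(in_a)[1:20]
  for (i in cells) {
    Ti <- sum(sim$counts$values[i, ])
    expect_lt(abs(sum(half$values[i, ]) - 0.5 * Ti), 5 * sqrt(0.25 * Ti) + 1)
  }
  expect_error(downsample_batch(sim$counts, split, "Z", 0.5), "not present")
  expect_error(downsample_batch(sim$counts, split, "A", 0), "p must")
})

test_that("invalid simulation configurations name the offending field", {
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(mito_gene_fraction = 2), "mito_gene_fraction")
  expect_error(sim_config(n_genes = 10, n_cell_types = 3,
                          marker_genes_per_type = 10),
               "marker_genes_per_type")
})
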