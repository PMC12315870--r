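test_that("identity corrector returns its input unchanged and is idempotent", {
  sim <- small_sim(n_cells = 80, n_genes = 80)
  norm <- normalize_log(sim$counts)
  emb <- suppressWarnings(pca_embed(norm, 1:80, 10))

  r1 <- identity_corrector(sim$counts)
  expect_equal(r1$tag, "counts")
  expect_identical(r1$payload$values, sim$counts$values)

  r2 <- identity_corrector(emb)
  expect_equal(r2$tag, "embedding")
  expect_identical(r2$payload, emb)

  r3 <- identity_corrector(identity_corrector(sim$counts)$payload)
  expect_identical(r3$payload$values, sim$counts$values)
})

test_that("correction results are validated: NaN, cell-set and sign checks", {
  sim <- small_sim(n_cells = 60, n_genes = 80)
  split <- random_split(60, seed = 1)

  register_corrector("nan_corrector", "embedding",
                     function(obj, batches, options) {
                       obj[1, 1] <- NaN
                       obj
                     }, overwrite = TRUE)
  norm <- normalize_log(sim$counts)
  emb <- suppressWarnings(pca_embed(norm, 1:80, 10))
  expect_error(
    apply_corrector(corrector_spec("nan_corrector"), sim$counts, norm, emb,
                    NULL, split),
    "non-finite")

  register_corrector("drop_cell", "raw-counts",
                     function(obj, batches, options)
                       count_matrix(obj$values[-1, , drop = FALSE],
                                    obj$cell_ids[-1], obj$gene_ids),
                     overwrite = TRUE)
  expect_error(
    apply_corrector(corrector_spec("drop_cell"), sim$counts, norm, emb,
                    NULL, split),
    "cell universe")

  # a corrector that bypasses the count_matrix constructor to smuggle a
  # negative entry must be caught by result validation
  register_corrector("negative2", "raw-counts",
                     function(obj, batches, options) {
                       obj$values[1, 1] <- -5
                       obj
                     }, overwrite = TRUE)
  expect_error(
    apply_corrector(corrector_spec("negative2"), sim$counts, norm, emb,
                    NULL, split),
    "negative")
})

test_that("a cell-shuffling corrector is re-aligned and leaves metrics unchanged", {
  sim <- small_sim(n_cells = 120, n_genes = 100, marker_genes_per_type = 40)
  split <- random_split(120, seed = 3)
  norm <- normalize_log(sim$counts)
  emb <- suppressWarnings(pca_embed(norm, 1:100, 20))

  register_corrector("shuffler", "embedding",
                     function(obj, batches, options) {
                       perm <- rev(seq_len(nrow(obj)))
                       obj[perm, , drop = FALSE]
                     }, overwrite = TRUE)
  res <- apply_corrector(corrector_spec("shuffler"), sim$counts, norm, emb,
                         NULL, split)
  expect_identical(rownames(res$payload), rownames(emb))
  expect_equal(res$payload, emb, ignore_attr = TRUE)
  rd <- rank_displacement(emb, res$payload, k = 10)
  expect_equal(rd$median, 0)
})

test_that("location-scale correction equalizes batch moments per gene", {
  # gene with batch means 0 and 2, equal variance and size -> both means 1
  set.seed(5)
  x <- c(rnorm(50, 0, 1), rnorm(50, 2, 1))
  nm <- structure(list(values = matrix(x, ncol = 1), target_sum = 1e4,
                       cell_totals = rep(1, 100),
                       cell_ids = paste0("c", 1:100), gene_ids = "g"),
                  class = "norm_matrix")
  batches <- rep(c("A", "B"), each = 50)
  res <- location_scale_corrector(nm, batches)
  out <- res$payload$values[, 1]
  pooled_mean <- mean(x)
  expect_equal(mean(out[1:50]), pooled_mean, tolerance = 1e-10)
  expect_equal(mean(out[51:100]), pooled_mean, tolerance = 1e-10)

  # constant gene is unchanged
  nm2 <- nm; nm2$values <- cbind(nm$values, 3)
  nm2$gene_ids <- c("g", "const")
  res2 <- location_scale_corrector(nm2, batches)
  expect_equal(res2$payload$values[, 2], rep(3, 100))

  # identical batch distributions, unit variance, n = 2000: correction is
  # near-identity (deviation bounded by moment sampling error)
  set.seed(9)
  vals <- matrix(rnorm(2000 * 20), 2000, 20)
  nmb <- structure(list(values = vals, target_sum = 1e4,
                        cell_totals = rep(1, 2000),
                        cell_ids = paste0("c", 1:2000),
                        gene_ids = paste0("g", 1:20)),
                   class = "norm_matrix")
  sp <- random_split(2000, seed = 12)
  res3 <- location_scale_corrector(nmb, sp)
  # oracle bound from moment sampling error: per gene and batch, the
  # deviation is at most max|x - m_b| * |s_pool/s_b - 1| + |m_pool - m_b|,
  # whose terms are bounded (4 sigma) by the standard errors of the sample
  # sd ratio and mean difference under identical distributions
  for (b in c("A", "B")) {
    ix <- sp == b
    n_b <- sum(ix); n <- 2000
    se_kappa <- sqrt(1 / (2 * n_b) + 1 / (2 * n))
    se_mean <- sqrt(1 / n_b - 1 / n)
    dev_b <- abs(res3$payload$values[ix, ] - vals[ix, ])
    for (g in 1:20) {
      m_b <- mean(vals[ix, g])
      bound <- max(abs(vals[ix, g] - m_b)) * 4 * se_kappa + 4 * se_mean
      expect_lt(max(dev_b[, g]), bound)
    }
  }

  expect_error(location_scale_corrector(nm, c("A", rep("B", 99))),
               "fewer than two")
})

test_that("oracle inverse exactly undoes a deterministic injection", {
  sim <- small_sim(n_cells = 200, n_genes = 150, marker_genes_per_type = 40)
  split <- random_split(200, seed = 6)
  norm0 <- normalize_log(sim$counts)

  pert <- inject_batch_effect(sim$counts, split, 1:30, 0.5, mode = "exact")
  eff <- attr(pert, "injected_effect")
  normp <- normalize_log(pert)
  res <- oracle_inverse_corrector(normp, split,
                                  options = list(injected_effect = eff))
  expect_equal(res$payload$values, norm0$values, tolerance = 1e-9)

  # rank displacement after inversion is zero everywhere
  emb0 <- suppressWarnings(pca_embed(norm0, 1:150, 20))
  embr <- suppressWarnings(pca_embed(res$payload, 1:150, 20))
  rd <- rank_displacement(emb0, embr, k = 15)
  expect_true(all(rd$per_cell == 0))

  # factor-1 "injection" composes with the oracle to the identity
  pert1 <- inject_batch_effect(sim$counts, split, 1:30, 1, mode = "exact")
  res1 <- oracle_inverse_corrector(normalize_log(pert1), split,
                                   options = list(
                                     injected_effect = attr(pert1, "injected_effect")))
  expect_equal(res1$payload$values, norm0$values, tolerance = 1e-12)

  expect_error(oracle_inverse_corrector(normp, split, options = list()),
               "missing injected_effect")
  thin <- inject_batch_effect(sim$counts, split, 1:30, 0.5, mode = "thin")
  expect_error(
    oracle_inverse_corrector(normalize_log(thin), split,
                             options = list(injected_effect = attr(thin, "injected_effect"))),
    "exact-mode")
})

test_that("registry rejects duplicate ids and unknown correctors", {
  expect_error(register_corrector("identity", "raw-counts", identity),
               "already registered")
  expect_error(corrector_spec("no_such_method"), "not registered")
  expect_true(all(c("identity", "location_scale", "oracle_inverse") %in%
                    list_correctors()))
})
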