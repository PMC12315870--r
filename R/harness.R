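# Pseudobatch calibration harness. One dataset with no true batch effect is
# randomly split into two pseudobatches; a corrector is applied; every
# downstream pipeline stage is rebuilt from the corrected object and
# compared against the uncorrected ground truth. Repeated over iterations,
# medians reported.

#' Random pseudobatch split
#'
#' Uniformly random (seeded) assignment of cells to two batches of equal
#' size: the first `ceiling(n/2)` cells of a random permutation go to "A",
#' the rest to "B". With odd n the extra cell goes to "A".
#'
#' @param n_cells number of cells (>= 2).
#' @param seed RNG seed.
#' @return character vector of labels in `{"A", "B"}` with attribute `seed`.
#' @export
random_split <- function(n_cells, seed = 1L) {
  if (n_cells < 2) stop("need at least two cells to split", call. = FALSE)
  labels <- rep("B", n_cells)
  perm <- with_seed(seed, sample.int(n_cells))
  labels[perm[seq_len(ceiling(n_cells / 2))]] <- "A"
  structure(labels, seed = as.integer(seed))
}

default_run_config <- function() {
  list(n_hvg = 2000, n_pcs = 50, k = 15, k_rank = 30, resolution = 1.0,
       target_sum = 1e4, alpha = 0.05, fc_thresh = 0.6, ridge = 1e-3,
       de_markers = NULL, de_top_n = 200, de = TRUE, perturbation = NULL)
}

# Resolve a perturbation block against the ground-truth pipeline and apply
# it to the raw counts of one batch.
apply_perturbation <- function(counts, gt, split, pert, seed) {
  if (is.null(pert)) return(counts)
  type <- match.arg(pert$type, c("inject", "downsample"))
  if (type == "downsample") {
    return(downsample_batch(counts, split, batch = pert$batch %||% "B",
                            p = pert$p, seed = seed))
  }
  genes <- pert$genes
  if (is.null(genes)) {
    target <- pert$target_cluster
    if (is.null(target) && !is.null(pert$target_marker)) {
      target <- identify_cluster_by_marker(gt$norm, gt$clustering,
                                           pert$target_marker)
    }
    if (is.null(target))
      stop("inject perturbation needs genes, target_cluster or target_marker",
           call. = FALSE)
    genes <- select_perturbation_targets(counts, gt$clustering, target,
                                         n_genes = pert$n_genes %||% 100)
  }
  inject_batch_effect(counts, split, genes, factor = pert$factor,
                      seed = seed, batch = pert$batch %||% "B",
                      mode = pert$mode %||% "thin")
}

# All DE comparisons for one iteration. Returns scalar metrics plus the
# volcano table, or a skip record when marker matching fails.
iteration_de <- function(gt, split, norm_c, clust_c, cfg) {
  mk <- cfg$de_markers
  resolve_pair <- function(norm, clustering) {
    gidx <- match(mk, norm$gene_ids)
    if (any(is.na(gidx)))
      stop(sprintf("marker gene(s) %s not present",
                   paste(mk[is.na(gidx)], collapse = ", ")), call. = FALSE)
    sc <- marker_score_matrix(norm$values, as.character(unclass(clustering)))
    vapply(gidx, function(g) {
      lab <- identify_from_scores(sc, g, cfg$de_top_n)
      if (is.null(lab))
        stop(structure(class = c("batchcal_marker_not_found", "error",
                                 "condition"),
                       list(message = sprintf(
                         "gene '%s' is not a top-%d marker of any cluster",
                         norm$gene_ids[g], cfg$de_top_n), call = NULL)))
      lab
    }, "")
  }
  run_three <- function(norm, clustering, pair, source) {
    run_de_designs(norm, clustering, split, pair, genes = gt$hvg,
                   alpha = cfg$alpha, fc_thresh = cfg$fc_thresh,
                   ridge = cfg$ridge, counts_source = source)
  }
  pair_gt <- resolve_pair(gt$norm, gt$clustering)
  if (pair_gt[1] == pair_gt[2])
    stop(structure(class = c("batchcal_marker_not_found", "error", "condition"),
                   list(message = "both markers resolve to the same cluster",
                        call = NULL)))
  before <- run_three(gt$norm, gt$clustering, pair_gt, "corrected")

  out <- list(metrics = c(
    de_nsig_before_cluster = sum(before$cluster$significant),
    de_nsig_before_bc_cluster = sum(before$bc_cluster$significant),
    de_nsig_before_bc_batch = sum(before$bc_batch$significant)))

  sources <- list()
  if (!is.null(norm_c)) sources$corrected <- norm_c
  sources$`uncorrected-with-corrected-clusters` <- gt$norm
  key <- c(corrected = "corr", `uncorrected-with-corrected-clusters` = "uncorr")
  volcano <- NULL
  for (src in names(sources)) {
    pair_c <- resolve_pair(sources[[src]], clust_c)
    after <- run_three(sources[[src]], clust_c, pair_c, src)
    kk <- key[[src]]
    m <- c(sum(after$cluster$significant),
           sum(after$bc_cluster$significant),
           sum(after$bc_batch$significant),
           de_overlap(before$cluster, after$cluster))
    names(m) <- paste0(c("de_nsig_after_", "de_nsig_after_bc_cluster_",
                         "de_nsig_after_bc_batch_", "de_overlap_"),
                       kk)
    names(m)[1] <- paste0("de_nsig_after_cluster_", kk)
    out$metrics <- c(out$metrics, m)
    if (src == names(sources)[1]) {
      volcano <- data.frame(gene = before$cluster$gene,
                            gene_id = before$cluster$gene_id,
                            p_before = before$cluster$p,
                            fc_before = before$cluster$log2fc,
                            class_before = before$cluster$class,
                            p_after = after$cluster$p,
                            fc_after = after$cluster$log2fc,
                            class_after = after$cluster$class,
                            stringsAsFactors = FALSE)
    }
  }
  out$volcano <- volcano
  out$pair <- pair_gt
  out
}

#' Run one calibration iteration
#'
#' Executes the full evaluation loop once: ground-truth preprocessing on the
#' unaltered counts, random pseudobatch split, optional perturbation
#' (batch-effect injection or downsampling), correction, rebuilding of the
#' downstream objects appropriate to what the corrector returns, and all
#' applicable metrics against ground truth. Metrics that do not apply to
#' the corrected object (rank displacement for graph-only correctors;
#' corrected-counts DE for embedding correctors) are recorded as skipped
#' with a reason.
#'
#' @param counts QC-filtered [count_matrix()].
#' @param spec a [corrector_spec()].
#' @param config run configuration list (see [calibrate()] for fields);
#'   missing fields take defaults.
#' @param seed iteration seed (drives the split, Leiden, perturbation).
#' @return list of class `calibration_iteration` with `seed`, `status`,
#'   `metrics` (named numeric), `skipped` (named character reasons),
#'   `details` (confusion matrices, volcano table, ...).
#' @export
run_iteration <- function(counts, spec, config = list(), seed = 1L) {
  cfg <- modifyList(default_run_config(), config)
  gt <- preprocess(counts, n_hvg = min(cfg$n_hvg, ncol(counts$values)),
                   n_pcs = cfg$n_pcs, k = cfg$k,
                   resolution = cfg$resolution, seed = seed,
                   target_sum = cfg$target_sum)
  split <- random_split(nrow(counts$values), seed = seed)

  counts_p <- apply_perturbation(counts, gt, split, cfg$perturbation, seed)
  perturbed <- !identical(counts_p$values, counts$values)
  if (perturbed) {
    norm_p <- normalize_log(counts_p, target_sum = cfg$target_sum)
    emb_p <- suppressWarnings(pca_embed(norm_p, gt$hvg, cfg$n_pcs))
    graph_p <- knn_graph(emb_p, k = cfg$k)
  } else {
    norm_p <- gt$norm; emb_p <- gt$embedding; graph_p <- gt$graph
  }
  # exact-mode injections carry the record the oracle-inverse corrector needs
  eff <- attr(counts_p, "injected_effect")
  if (!is.null(eff) && is.null(spec$options$injected_effect)) {
    spec$options$injected_effect <- eff
  }
  corr <- apply_corrector(spec, counts_p, norm_p, emb_p, graph_p, split)

  skipped <- character(0)
  norm_c <- NULL; emb_c <- NULL
  if (corr$tag == "counts") {
    norm_c <- if (inherits(corr$payload, "count_matrix"))
      normalize_log(corr$payload, target_sum = cfg$target_sum) else corr$payload
    emb_c <- suppressWarnings(
      pca_embed(norm_c, gt$hvg, cfg$n_pcs,
                provenance = "pca-on-corrected-counts"))
    graph_c <- knn_graph(emb_c, k = cfg$k)
  } else if (corr$tag == "embedding") {
    emb_c <- corr$payload
    graph_c <- knn_graph(emb_c, k = cfg$k)
  } else {
    graph_c <- corr$payload
  }
  clust_c <- leiden_cluster(graph_c, resolution = cfg$resolution, seed = seed)

  metrics <- c(ari = adjusted_rand_index(gt$clustering, clust_c))
  details <- list()

  if (!is.null(emb_c)) {
    rd <- rank_displacement(gt$embedding, emb_c,
                            k = min(cfg$k_rank, nrow(counts$values) - 1))
    metrics["rank_disp_median"] <- rd$median
    details$rank_displacement <- rd
  } else {
    skipped["rank_disp_median"] <- "corrector returns k-NN graph"
  }

  conf <- cluster_confusion(gt$clustering, clust_c)
  perm <- match_columns(conf)
  imb <- batch_imbalance(gt$clustering, clust_c, split)
  big <- !imb$dimmed & conf > 0
  metrics["imbalance_dev"] <- if (any(big))
    max(abs(imb$ratio[big] - 0.5)) else NA_real_
  details$confusion <- conf[, perm, drop = FALSE]
  details$imbalance <- list(ratio = imb$ratio[, perm, drop = FALSE],
                            dimmed = imb$dimmed[, perm, drop = FALSE])

  if (isTRUE(cfg$de) && !is.null(cfg$de_markers)) {
    de <- tryCatch(iteration_de(gt, split, norm_c, clust_c, cfg),
                   batchcal_marker_not_found = function(e) e)
    if (inherits(de, "condition")) {
      skipped["de"] <- conditionMessage(de)
    } else {
      metrics <- c(metrics, de$metrics)
      details$volcano <- de$volcano
      details$de_pair <- de$pair
    }
  } else if (isTRUE(cfg$de)) {
    skipped["de"] <- "no de_markers configured"
  }

  structure(list(seed = as.integer(seed), status = "ok", metrics = metrics,
                 skipped = skipped, details = details),
            class = "calibration_iteration")
}

#' Calibration experiment for one correction method
#'
#' The package's main entry point. Repeats [run_iteration()] with seeds
#' `base_seed + 1 .. base_seed + n_iterations` and aggregates per-iteration
#' scalar metrics into across-iteration medians. An iteration whose
#' corrector raises is recorded as failed and excluded from the medians;
#' the experiment errors only if every iteration failed.
#'
#' @param counts QC-filtered [count_matrix()] (apply [qc_filter()] first).
#' @param corrector corrector id (see [list_correctors()]) or a
#'   [corrector_spec()].
#' @param corrector_options options list passed to the corrector.
#' @param n_iterations number of pseudobatch iterations (default 25).
#' @param base_seed base RNG seed; iteration i uses `base_seed + i`.
#' @param n_hvg,n_pcs,k,resolution,target_sum preprocessing parameters
#'   (highly variable genes, PCA components, k-NN neighbors, Leiden
#'   resolution, normalization target).
#' @param k_rank neighbors per cell in the rank-displacement statistic
#'   (default 30).
#' @param de_markers character vector of two marker gene ids identifying
#'   the compared cell-type clusters (e.g. `c("MS4A1", "CD8A")` for B vs
#'   CD8+ T cells); `NULL` skips the DE stage.
#' @param de run the differential-expression stage at all.
#' @param de_top_n marker-ranking depth for cluster identification.
#' @param alpha family-wise significance level before Bonferroni division.
#' @param fc_thresh volcano log2 fold-change threshold.
#' @param ridge logistic ridge penalty in the hurdle model.
#' @param perturbation optional perturbation block:
#'   `list(type = "inject", factor =, n_genes =, target_marker = | genes =,
#'   mode =)` or `list(type = "downsample", p =)`.
#' @return an object of class `calibration_report`.
#' @export
calibrate <- function(counts, corrector = "identity",
                      corrector_options = list(), n_iterations = 25,
                      base_seed = 1L, n_hvg = 2000, n_pcs = 50, k = 15,
                      k_rank = 30, resolution = 1.0, target_sum = 1e4,
                      de_markers = NULL, de = TRUE, de_top_n = 200,
                      alpha = 0.05, fc_thresh = 0.6, ridge = 1e-3,
                      perturbation = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  spec <- if (inherits(corrector, "corrector_spec")) corrector
          else corrector_spec(corrector, corrector_options)
  cfg <- list(n_hvg = n_hvg, n_pcs = n_pcs, k = k, k_rank = k_rank,
              resolution = resolution, target_sum = target_sum,
              de_markers = de_markers, de = de, de_top_n = de_top_n,
              alpha = alpha, fc_thresh = fc_thresh, ridge = ridge,
              perturbation = perturbation)
  iterations <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    iterations[[i]] <- tryCatch(
      run_iteration(counts, spec, cfg, seed = base_seed + i),
      error = function(e) structure(
        list(seed = as.integer(base_seed + i), status = "failed",
             metrics = numeric(0), skipped = character(0),
             error = conditionMessage(e), details = list()),
        class = "calibration_iteration"))
  }
  ok <- vapply(iterations, function(x) x$status == "ok", TRUE)
  if (!any(ok)) stop("all iterations failed; first error: ",
                     iterations[[1]]$error, call. = FALSE)
  metric_names <- unique(unlist(lapply(iterations[ok],
                                       function(x) names(x$metrics))))
  tab <- vapply(iterations, function(x) {
    v <- rep(NA_real_, length(metric_names))
    names(v) <- metric_names
    if (x$status == "ok") v[names(x$metrics)] <- x$metrics
    v
  }, numeric(length(metric_names)))
  tab <- matrix(tab, nrow = length(metric_names),
                dimnames = list(metric_names, NULL))
  medians <- apply(tab, 1, median, na.rm = TRUE)
  structure(list(corrector = spec$id, corrector_options = corrector_options,
                 n_iterations = n_iterations, base_seed = as.integer(base_seed),
                 iterations = iterations, metrics = t(tab),
                 medians = medians, n_failed = sum(!ok), config = cfg,
                 fingerprint = counts_fingerprint(counts)),
            class = "calibration_report")
}

#' @rdname calibrate
#' @export
run_experiment <- calibrate

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report: corrector '%s', %d iteration(s)%s\n",
              x$corrector, x$n_iterations,
              if (x$n_failed) sprintf(" (%d failed)", x$n_failed) else ""))
  cat("Across-iteration medians:\n")
  print(round(x$medians, 4))
  invisible(x)
}

#' @export
summary.calibration_report <- function(object, ...) {
  cat(sprintf("Pseudobatch calibration of corrector '%s'\n", object$corrector))
  cat(sprintf("  iterations: %d ok, %d failed (base seed %d)\n",
              object$n_iterations - object$n_failed, object$n_failed,
              object$base_seed))
  cat(sprintf("  dataset fingerprint: %s\n", object$fingerprint))
  cat("  per-iteration metrics (median [min, max]):\n")
  for (m in colnames(object$metrics)) {
    v <- object$metrics[, m]
    cat(sprintf("    %-32s %8.3f [%.3f, %.3f]\n", m,
                median(v, na.rm = TRUE), suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
  }
  skips <- unlist(lapply(object$iterations, function(x) x$skipped))
  if (length(skips))
    cat("  skipped:", paste(unique(paste0(names(skips), " (", skips, ")")),
                            collapse = "; "), "\n")
  invisible(object)
}

#' @export
as.data.frame.calibration_report <- function(x, ...) {
  d <- as.data.frame(x$metrics)
  d <- cbind(iteration = seq_len(nrow(d)),
             seed = vapply(x$iterations, `[[`, 0L, "seed"),
             status = vapply(x$iterations, `[[`, "", "status"), d)
  rownames(d) <- NULL
  d
}

#' Plot a calibration report
#'
#' Draws the matched before/after cluster confusion matrix of one iteration
#' as a heat-map pair: cell counts on the left, batch-A ratio on the right
#' with squares of fewer than 10 cells dimmed. A perfectly calibrated
#' corrector shows a purely diagonal left panel and a uniform 0.5 right
#' panel.
#'
#' @param x a `calibration_report`.
#' @param iteration which iteration to draw (default first successful).
#' @param ... unused.
#' @export
plot.calibration_report <- function(x, iteration = NULL, ...) {
  ok <- which(vapply(x$iterations, function(i) i$status == "ok", TRUE))
  iteration <- iteration %||% ok[1]
  det <- x$iterations[[iteration]]$details
  if (is.null(det$confusion)) stop("iteration has no confusion matrix",
                                   call. = FALSE)
  conf <- det$confusion
  ratio <- det$imbalance$ratio
  dim_sq <- det$imbalance$dimmed
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(old))
  img <- function(m, main, col) {
    image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                                                  drop = FALSE]),
          col = col, axes = FALSE, xlab = "cluster after",
          ylab = "cluster before", main = main)
    axis(1, seq_len(ncol(m)), colnames(m)); axis(2, rev(seq_len(nrow(m))),
                                                 rownames(m), las = 1)
    box()
  }
  img(conf, sprintf("cells (iteration %d)", iteration),
      hcl.colors(32, "Blues 3", rev = TRUE))
  r <- ratio
  r[dim_sq & !is.na(r)] <- NA   # dim tiny squares
  img(r, "batch-A ratio (small squares dimmed)",
      hcl.colors(32, "Blue-Red 2"))
  invisible(x)
}
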