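#' Simulation configuration
#'
#' Parameters of the negative-binomial UMI count simulator. Defaults are the
#' study conditions used throughout the package's own experiments: a
#' medium-sized droplet-style dataset with a few transcriptionally distinct
#' cell types, overdispersed counts, log-normal library-size variation and a
#' small fraction of mitochondrial genes.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param n_cell_types number of cell types.
#' @param marker_genes_per_type number of marker genes specific to each type
#'   (marker sets are disjoint; `n_cell_types * marker_genes_per_type` must
#'   not exceed `n_genes`).
#' @param marker_log2fc log2 fold change of a marker gene inside its own
#'   type relative to all other types (>= 0).
#' @param base_mean expected base counts per gene per cell; per-gene means
#'   are gamma-distributed around this value.
#' @param gamma_shape shape of the gamma distribution of per-gene base means
#'   (scale is `base_mean / gamma_shape`).
#' @param dispersion negative-binomial shape (`size`); smaller is more
#'   overdispersed.
#' @param libsize_sigma standard deviation of log library-size factors
#'   (log-normal, mean 0 on the log scale).
#' @param mito_gene_fraction fraction of genes named with the "MT-" prefix
#'   (floor rounding).
#' @param seed RNG seed; the simulation is bit-reproducible given the
#'   configuration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 1000, n_cell_types = 3,
                       marker_genes_per_type = 50, marker_log2fc = 2,
                       base_mean = 1, gamma_shape = 2, dispersion = 1,
                       libsize_sigma = 0.35, mito_gene_fraction = 0.02,
                       seed = 1L) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_cell_types = n_cell_types,
              marker_genes_per_type = marker_genes_per_type,
              marker_log2fc = marker_log2fc, base_mean = base_mean,
              gamma_shape = gamma_shape, dispersion = dispersion,
              libsize_sigma = libsize_sigma,
              mito_gene_fraction = mito_gene_fraction, seed = seed)
  chk_pos_int <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v))
      stop_config(f, "must be a positive integer")
  }
  chk_pos_int("n_cells"); chk_pos_int("n_genes"); chk_pos_int("n_cell_types")
  m <- cfg$marker_genes_per_type
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0 || m != floor(m))
    stop_config("marker_genes_per_type", "must be a non-negative integer")
  if (cfg$n_cell_types * m > cfg$n_genes)
    stop_config("marker_genes_per_type",
                "requires n_cell_types * marker_genes_per_type <= n_genes")
  chk_nonneg <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_config(f, "must be a non-negative real")
  }
  chk_pos <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop_config(f, "must be a strictly positive real")
  }
  chk_nonneg("marker_log2fc"); chk_nonneg("libsize_sigma")
  chk_pos("base_mean"); chk_pos("gamma_shape"); chk_pos("dispersion")
  mf <- cfg$mito_gene_fraction
  if (!is.numeric(mf) || length(mf) != 1 || is.na(mf) || mf < 0 || mf > 1)
    stop_config("mito_gene_fraction", "must lie in [0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")
  structure(cfg, class = "sim_config")
}

#' Simulate a UMI count matrix with known cell-type structure
#'
#' Counts for cell i and gene g are drawn from a negative binomial with mean
#' `s_i * mu_g * f(type(i), g)` where `s_i` is a log-normal library-size
#' factor, `mu_g` a gamma-distributed per-gene base mean around
#' `base_mean`, and `f = 2^marker_log2fc` when g is a marker gene of the
#' cell's type (1 otherwise). The last `floor(mito_gene_fraction * n_genes)`
#' genes are named with the "MT-" prefix; marker genes are always drawn from
#' the non-mitochondrial block. Cell types are balanced (round-robin, then
#' shuffled).
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (a [count_matrix()]) and `truth`,
#'   where `truth` is a list with `cell_type_of_cell` (character per cell),
#'   `marker_genes_of_type` (named list of 1-based gene index vectors) and
#'   `injected_effect` (`NULL`; filled by [inject_batch_effect()]).
#' @export
simulate_counts <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_cells; G <- config$n_genes; Tt <- config$n_cell_types
  m <- config$marker_genes_per_type
  n_mito <- floor(config$mito_gene_fraction * G)
  if (Tt * m > G - n_mito)
    stop_config("marker_genes_per_type",
                "markers must fit among non-mitochondrial genes")
  with_seed(config$seed, {
    type <- sample(rep_len(seq_len(Tt), n))
    mu <- rgamma(G, shape = config$gamma_shape,
                 scale = config$base_mean / config$gamma_shape)
    s <- exp(rnorm(n, 0, config$libsize_sigma))
    markers <- lapply(seq_len(Tt), function(t) {
      if (m == 0) integer(0) else ((t - 1) * m + 1):(t * m)
    })
    fc <- 2^config$marker_log2fc
    mean_mat <- outer(s, mu)
    for (t in seq_len(Tt)) {
      if (length(markers[[t]]))
        mean_mat[type == t, markers[[t]]] <-
          mean_mat[type == t, markers[[t]], drop = FALSE] * fc
    }
    vals <- matrix(rnbinom(n * G, size = config$dispersion, mu = mean_mat), n, G)
    gene_ids <- paste0("GENE", seq_len(G))
    if (n_mito > 0)
      gene_ids[(G - n_mito + 1):G] <- paste0("MT-", seq_len(n_mito))
    counts <- count_matrix(vals, cell_ids = paste0("cell", seq_len(n)),
                           gene_ids = gene_ids)
    type_labels <- paste0("type", seq_len(Tt))
    names(markers) <- type_labels
    list(counts = counts,
         truth = list(cell_type_of_cell = type_labels[type],
                      marker_genes_of_type = markers,
                      injected_effect = NULL))
  })
}

#' Inject a targeted batch effect into a count matrix
#'
#' Reduces the counts of a chosen gene set, for the cells of one batch only,
#' by a multiplicative factor. The default mode `"thin"` replaces each count
#' c by a Binomial(c, factor) draw, keeping counts integer-valued;
#' `"exact"` multiplies deterministically (possibly fractional), which makes
#' the perturbation exactly invertible and is used by the oracle-inverse
#' corrector in tests. All other entries are untouched.
#'
#' @param counts a [count_matrix()].
#' @param batches batch labels from [random_split()] (or any two-level
#'   labelling of the cells).
#' @param genes integer vector of gene indices to perturb.
#' @param factor multiplicative factor in (0, 1].
#' @param seed RNG seed for the binomial draws (ignored in exact mode).
#' @param batch which batch label receives the perturbation; defaults to the
#'   second level.
#' @param mode `"thin"` (binomial thinning) or `"exact"`.
#' @return a [count_matrix()] with an `injected_effect` attribute recording
#'   genes, batch, factor, mode and seed.
#' @export
inject_batch_effect <- function(counts, batches, genes, factor, seed = 1L,
                                batch = NULL, mode = c("thin", "exact")) {
  stopifnot(inherits(counts, "count_matrix"))
  mode <- match.arg(mode)
  labs <- unique(batches)
  if (length(labs) != 2)
    stop("exactly two batch labels must be present", call. = FALSE)
  if (length(batches) != nrow(counts$values))
    stop("batch labels must cover all cells", call. = FALSE)
  batch <- batch %||% sort(labs)[2]
  if (!batch %in% labs) stop("batch label not present", call. = FALSE)
  genes <- as.integer(genes)
  if (length(genes) && (any(is.na(genes)) || any(genes < 1) ||
                        any(genes > ncol(counts$values))))
    stop("unknown gene index", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) ||
      factor <= 0 || factor > 1)
    stop("factor must lie in (0, 1]", call. = FALSE)
  out <- counts
  cells <- which(batches == batch)
  if (length(genes) && length(cells) && factor < 1) {
    sub <- counts$values[cells, genes, drop = FALSE]
    if (mode == "thin") {
      thinned <- with_seed(seed, {
        matrix(rbinom(length(sub), size = as.integer(sub), prob = factor),
               nrow(sub), ncol(sub))
      })
    } else {
      thinned <- sub * factor
    }
    out$values[cells, genes] <- thinned
    dimnames(out$values) <- dimnames(counts$values)
  }
  attr(out, "injected_effect") <- list(genes = genes, batch = batch,
                                       factor = factor, mode = mode,
                                       seed = as.integer(seed))
  out
}

#' Select perturbation target genes for a cluster
#'
#' Returns the `n_genes` genes most differentially expressed in
#' `target_cluster` versus the rest (smallest one-vs-rest rank-sum p-value,
#' ties broken by gene index), the gene set the injected batch effect is
#' applied to.
#'
#' @param counts a [count_matrix()].
#' @param clustering cluster label per cell (typically from an ad hoc run of
#'   the preprocessing pipeline on the same counts).
#' @param target_cluster label of the cluster whose markers are targeted.
#' @param n_genes number of genes to return (default 100).
#' @return integer vector of gene indices, length `min(n_genes, n_total)`.
#' @export
select_perturbation_targets <- function(counts, clustering, target_cluster,
                                        n_genes = 100) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!target_cluster %in% clustering)
    stop("target_cluster not present in clustering", call. = FALSE)
  if (n_genes == 0) return(integer(0))
  norm <- normalize_log(counts)
  p <- wilcox_marker_pvalues(norm$values, clustering == target_cluster)
  G <- ncol(counts$values)
  if (n_genes > G) {
    warning(sprintf("only %d genes available; returning all", G))
    n_genes <- G
  }
  order(p, seq_len(G))[seq_len(n_genes)]
}

#' Downsample one batch by binomial thinning
#'
#' Every count of every gene for cells in the chosen batch is replaced by a
#' Binomial(c, p) draw, emulating sequencing one batch to a fraction of its
#' depth; other cells are untouched.
#'
#' @param counts a [count_matrix()].
#' @param batches batch label per cell.
#' @param batch label of the batch to thin.
#' @param p retention probability in (0, 1].
#' @param seed RNG seed.
#' @return a [count_matrix()].
#' @export
downsample_batch <- function(counts, batches, batch, p, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(batches) != nrow(counts$values))
    stop("batch labels must cover all cells", call. = FALSE)
  if (!batch %in% batches) stop("batch label not present", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1)
    stop("p must lie in (0, 1]", call. = FALSE)
  out <- counts
  if (p < 1) {
    cells <- which(batches == batch)
    sub <- counts$values[cells, , drop = FALSE]
    out$values[cells, ] <- with_seed(seed, {
      matrix(rbinom(length(sub), size = as.integer(sub), prob = p),
             nrow(sub), ncol(sub))
    })
    dimnames(out$values) <- dimnames(counts$values)
  }
  out
}
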