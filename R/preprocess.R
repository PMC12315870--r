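#' Quality-control filtering of cells and genes
#'
#' Removes cells with too few detected genes or a high mitochondrial count
#' fraction, then removes genes detected in too few of the remaining cells
#' (cell filter strictly before gene filter). Mitochondrial genes are
#' recognised by the "MT-" name prefix (case-insensitive).
#'
#' Defaults are the canonical PBMC-tutorial thresholds; all are
#' configuration, not biology.
#'
#' @param counts a [count_matrix()].
#' @param min_genes_per_cell keep cells detecting at least this many genes.
#' @param min_cells_per_gene keep genes detected in at least this many
#'   remaining cells.
#' @param max_mito_fraction keep cells whose mitochondrial count fraction is
#'   at most this value.
#' @return the filtered [count_matrix()].
#' @export
qc_filter <- function(counts, min_genes_per_cell = 200, min_cells_per_gene = 3,
                      max_mito_fraction = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]", call. = FALSE)
  v <- counts$values
  detected <- rowSums(v > 0)
  is_mito <- grepl("^MT-", counts$gene_ids, ignore.case = TRUE)
  tot <- rowSums(v)
  mito_frac <- ifelse(tot > 0, rowSums(v[, is_mito, drop = FALSE]) / tot, 0)
  keep_cells <- detected >= min_genes_per_cell & mito_frac <= max_mito_fraction
  if (!any(keep_cells)) stop("empty matrix after QC", call. = FALSE)
  v <- v[keep_cells, , drop = FALSE]
  keep_genes <- colSums(v > 0) >= min_cells_per_gene
  count_matrix(v[, keep_genes, drop = FALSE],
               cell_ids = counts$cell_ids[keep_cells],
               gene_ids = counts$gene_ids[keep_genes])
}

#' Library-size normalization with log transform
#'
#' Scales each cell to a common total count and applies log1p:
#' `value = ln(1 + count * target_sum / cell_total)`.
#'
#' @param counts a [count_matrix()] with no all-zero cells.
#' @param target_sum common library size after scaling (default 1e4).
#' @return an object of class `norm_matrix`: list with `values` (cells x
#'   genes), `target_sum`, `cell_totals`, `cell_ids`, `gene_ids`.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  if (target_sum <= 0) stop("target_sum must be positive", call. = FALSE)
  tot <- rowSums(counts$values)
  if (any(tot == 0)) {
    stop(sprintf("all-zero cell(s): %s",
                 paste(counts$cell_ids[tot == 0][1:min(3, sum(tot == 0))],
                       collapse = ", ")), call. = FALSE)
  }
  vals <- log1p(counts$values * (target_sum / tot))
  structure(list(values = vals, target_sum = target_sum, cell_totals = tot,
                 cell_ids = counts$cell_ids, gene_ids = counts$gene_ids),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("log-normalized matrix: %d cells x %d genes (target_sum %g)\n",
              nrow(x$values), ncol(x$values), x$target_sum))
  invisible(x)
}

#' Select highly variable genes
#'
#' Mean-binned normalized-dispersion selection (the Seurat-flavoured scheme
#' used by SCANPY's default): per gene, mean and dispersion (variance/mean)
#' are computed on the expm1 scale, genes are binned by mean (20 bins), the
#' dispersion is z-scored within bins, and the top `n` genes by normalized
#' dispersion are returned. Deterministic; ties broken by gene index. The
#' same list is intended to be reused for corrected data in all downstream
#' comparisons.
#'
#' @param norm a [normalize_log()] result.
#' @param n number of genes to select (default 2000).
#' @param n_bins number of mean bins for dispersion normalization.
#' @return integer vector of gene indices, most variable first.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  stopifnot(inherits(norm, "norm_matrix"))
  G <- ncol(norm$values)
  if (n > G) stop(sprintf("n (%d) exceeds gene count (%d)", n, G), call. = FALSE)
  x <- expm1(norm$values)
  mu <- colMeans(x)
  v <- colSums((x - rep(mu, each = nrow(x)))^2) / max(1, nrow(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # log-scale both axes, as in the reference workflow; zero-dispersion genes
  # sit at -Inf and can never outrank a gene with positive variance
  ldisp <- ifelse(disp > 0, log(disp), -Inf)
  lmu <- log1p(mu)
  bins <- cut(lmu, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  z <- ldisp
  for (b in unique(bins)) {
    ix <- which(bins == b)
    fin <- ldisp[ix][is.finite(ldisp[ix])]
    m <- if (length(fin)) mean(fin) else 0
    s <- if (length(fin) > 1) sd(fin) else 0
    z[ix] <- if (s > 0) (ldisp[ix] - m) / s else ifelse(is.finite(ldisp[ix]), 0, -Inf)
  }
  order(-z, seq_len(G))[seq_len(n)]
}

#' PCA embedding on a gene subset
#'
#' Column-centered PCA of the normalized matrix restricted to the given
#' genes. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so the embedding is
#' deterministic; neighbor ranks are invariant to this choice.
#'
#' @param norm a [normalize_log()] result.
#' @param genes gene indices (typically from [select_hvg()]).
#' @param n_components number of components (default 50). Reduced with a
#'   warning when the data cannot support that many.
#' @param provenance provenance tag stored on the embedding, one of
#'   `"pca-uncorrected"`, `"pca-on-corrected-counts"`,
#'   `"corrector-supplied"`.
#' @return an `embedding`: numeric matrix (cells x d) with attributes
#'   `provenance` and rownames = cell ids.
#' @export
pca_embed <- function(norm, genes = seq_len(ncol(norm$values)),
                      n_components = 50,
                      provenance = "pca-uncorrected") {
  x <- norm$values[, genes, drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  max_d <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_d) {
    warning(sprintf("n_components reduced from %d to %d (rank limit)",
                    n_components, max_d))
    n_components <- max_d
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  coords <- sv$u %*% (diag(sv$d[seq_len(n_components)], n_components) *
                        flip)
  rownames(coords) <- norm$cell_ids
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(coords, provenance = provenance, class = c("embedding", "matrix"))
}

#' Exact k-nearest-neighbor graph
#'
#' Exhaustive Euclidean k-NN in the embedding; self excluded; distance ties
#' broken by cell index ascending.
#'
#' @param embedding a cells x d coordinate matrix.
#' @param k number of neighbors (default 15, must be < number of cells).
#' @return a `knn_graph`: list with `idx` (n x k neighbor indices, nearest
#'   first), `dist` (matching distances), `k`, `cell_ids`.
#' @export
knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  D <- full_dist(embedding)
  diag(D) <- Inf
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ], seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- D[i, o]
  }
  structure(list(idx = idx, dist = dst, k = k,
                 cell_ids = rownames(embedding) %||% as.character(seq_len(n))),
            class = "knn_graph")
}

# Full pairwise Euclidean distance matrix via the cross-product identity,
# clamped at zero for numerical safety.
full_dist <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Leiden community detection on a k-NN graph
#'
#' Symmetrizes the k-NN graph and runs Leiden with the modularity objective
#' (the default partition type of the reference single-cell workflow) at the
#' given resolution. Deterministic given the seed. Cluster labels are
#' consecutive integers ordered by descending cluster size (ties by first
#' occurrence).
#'
#' @param graph a [knn_graph()].
#' @param resolution resolution parameter (default 1.0).
#' @param seed RNG seed.
#' @return a `clustering`: integer vector of labels per cell with attributes
#'   `resolution` and `seed`.
#' @export
leiden_cluster <- function(graph, resolution = 1.0, seed = 0L) {
  stopifnot(inherits(graph, "knn_graph"))
  n <- nrow(graph$idx)
  if (n == 0) stop("empty graph", call. = FALSE)
  el <- cbind(rep(seq_len(n), graph$k), as.vector(graph$idx))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution))
  })
  memb <- as.integer(memb)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  structure(relabel[memb], resolution = resolution, seed = as.integer(seed),
            cell_ids = graph$cell_ids, class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("clustering: %d cells in %d clusters (sizes %s)\n",
              length(x), length(tab), paste(tab, collapse = ", ")))
  invisible(x)
}

#' Run the uncorrected reference workflow
#'
#' Convenience wrapper chaining normalization, HVG selection, PCA, k-NN and
#' Leiden clustering, the pipeline that defines ground truth for every
#' calibration comparison. QC is expected to have been applied beforehand.
#'
#' @param counts a QC-filtered [count_matrix()].
#' @param n_hvg number of highly variable genes (capped at the gene count).
#' @param n_pcs number of principal components.
#' @param k neighbors in the k-NN graph.
#' @param resolution Leiden resolution.
#' @param seed seed for Leiden.
#' @param target_sum normalization target.
#' @return list with `norm`, `hvg`, `embedding`, `graph`, `clustering`.
#' @export
preprocess <- function(counts, n_hvg = 2000, n_pcs = 50, k = 15,
                       resolution = 1.0, seed = 0L, target_sum = 1e4) {
  norm <- normalize_log(counts, target_sum = target_sum)
  hvg <- select_hvg(norm, n = min(n_hvg, ncol(norm$values)))
  emb <- suppressWarnings(pca_embed(norm, hvg, n_components = n_pcs))
  g <- knn_graph(emb, k = k)
  cl <- leiden_cluster(g, resolution = resolution, seed = seed)
  list(norm = norm, hvg = hvg, embedding = emb, graph = g, clustering = cl)
}
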