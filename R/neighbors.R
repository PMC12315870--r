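# Nearest-neighbor rank displacement: how far do a cell's pre-correction
# neighbors drift down its distance ordering after correction.

#' Ranks of chosen neighbors among all cells
#'
#' For one cell, returns the 1-based position of each listed neighbor in the
#' ordering of all other cells by Euclidean distance from that cell (self
#' excluded, distance ties broken by cell index ascending). A neighbor's
#' rank can be anywhere in 1..n-1.
#'
#' @param embedding cells x d coordinate matrix with cell ids as rownames.
#' @param cell cell id (or index) of the reference cell.
#' @param neighbor_ids ids (or indices) of the neighbors to rank.
#' @return integer vector of ranks, one per neighbor.
#' @export
neighbor_ranks <- function(embedding, cell, neighbor_ids) {
  ids <- rownames(embedding) %||% as.character(seq_len(nrow(embedding)))
  ci <- resolve_cell(cell, ids)
  ni <- vapply(neighbor_ids, resolve_cell, 0L, ids = ids)
  d <- sqrt(colSums((t(embedding) - embedding[ci, ])^2))
  d[ci] <- Inf
  pos <- integer(length(d))
  pos[order(d, seq_along(d))] <- seq_along(d)
  pos[ni]
}

resolve_cell <- function(x, ids) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (is.na(x) || x < 1 || x > length(ids)) stop("unknown cell index", call. = FALSE)
    return(x)
  }
  i <- match(as.character(x), ids)
  if (is.na(i)) stop(sprintf("unknown cell id '%s'", x), call. = FALSE)
  i
}

#' Nearest-neighbor rank displacement between two embeddings
#'
#' For each cell, its top-k nearest neighbors in the `before` embedding
#' (ranks 1..k) are located in the `after` embedding's full distance
#' ordering, and the per-cell value is the median of the k absolute rank
#' differences. The summary statistic is the median of the per-cell values.
#' `before` is the uncorrected PCA embedding; `after` is the PCA on
#' corrected counts for count-returning correctors, or the
#' corrector-supplied embedding otherwise. Ranks are computed against all
#' cells, not just within the k-NN graph, so displaced neighbors can land
#' anywhere in 1..n-1. The statistic is invariant under rigid motions and
#' uniform scaling of either embedding.
#'
#' @param before cells x d embedding (uncorrected reference).
#' @param after cells x d embedding (post-correction), same cell set.
#' @param k neighbors per cell (default 30).
#' @return list of class `rank_displacement`: `per_cell` (named numeric),
#'   `median` (summary), `k`.
#' @export
rank_displacement <- function(before, after, k = 30) {
  ids_b <- rownames(before) %||% as.character(seq_len(nrow(before)))
  ids_a <- rownames(after) %||% as.character(seq_len(nrow(after)))
  if (!setequal(ids_b, ids_a) || nrow(before) != nrow(after))
    stop("embeddings must cover the same cell set", call. = FALSE)
  after <- after[match(ids_b, ids_a), , drop = FALSE]
  n <- nrow(before)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  Db <- full_dist(before); diag(Db) <- Inf
  Da <- full_dist(after); diag(Da) <- Inf
  per_cell <- numeric(n)
  sq <- seq_len(n)
  for (i in sq) {
    nb <- order(Db[i, ], sq)[seq_len(k)]
    pos <- integer(n)
    pos[order(Da[i, ], sq)] <- sq
    per_cell[i] <- median(abs(seq_len(k) - pos[nb]))
  }
  names(per_cell) <- ids_b
  structure(list(per_cell = per_cell, median = median(per_cell), k = k),
            class = "rank_displacement")
}

#' @export
print.rank_displacement <- function(x, ...) {
  cat(sprintf("rank displacement (k=%d): median %.1f over %d cells\n",
              x$k, x$median, length(x$per_cell)))
  invisible(x)
}
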