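# Cluster-level comparison of the partitions before and after correction:
# confusion matrix with optimal column matching, per-square batch imbalance,
# and the Adjusted Rand Index.

#' Cluster confusion matrix
#'
#' Entry (r, c) counts the cells in before-cluster r and after-cluster c.
#' Rows are ordered by descending before-cluster size; columns by after
#' label (use [match_columns()] to diagonalize).
#'
#' @param before,after cluster labels for the same cells.
#' @return integer matrix with dimnames set to cluster labels.
#' @export
cluster_confusion <- function(before, after) {
  if (length(before) != length(after))
    stop("clusterings must cover the same cells", call. = FALSE)
  tab <- table(before = unclass(before), after = unclass(after))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m[order(-rowSums(m), seq_len(nrow(m))), , drop = FALSE]
}

#' Optimal column matching of a confusion matrix
#'
#' Permutation of columns maximizing the diagonal sum (linear assignment;
#' rectangular matrices allowed). Surplus columns are appended in
#' descending column-total order. Makes the display "as diagonal as
#' possible" reproducibly, in place of manual ordering.
#'
#' @param confusion count matrix from [cluster_confusion()].
#' @return integer permutation of column indices.
#' @export
match_columns <- function(confusion) {
  if (!length(confusion)) stop("empty matrix", call. = FALSE)
  r <- nrow(confusion); c0 <- ncol(confusion)
  # only the first min(r, c) rows contribute diagonal entries
  assign <- hungarian_max(confusion[seq_len(min(r, c0)), , drop = FALSE])
  matched <- assign[!is.na(assign)]
  surplus <- setdiff(seq_len(c0), matched)
  if (length(surplus) > 1) {
    tot <- colSums(confusion)[surplus]
    surplus <- surplus[order(-tot, surplus)]
  }
  c(matched, surplus)
}

# Maximum-weight linear assignment via the Hungarian algorithm (potentials
# formulation, O(n^3)) on a padded square cost matrix. Returns, for each row
# in order, the assigned column; NA when the row is matched to padding.
hungarian_max <- function(w) {
  r <- nrow(w); c0 <- ncol(w)
  n <- max(r, c0)
  cost <- matrix(0, n, n)
  cost[seq_len(r), seq_len(c0)] <- max(w) - w
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_col <- integer(n)            # row -> column
  for (j in seq_len(n)) if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  out <- assign_col[seq_len(r)]
  out[out > c0] <- NA_integer_        # matched to padding
  out
}

#' Per-square batch imbalance of a confusion matrix
#'
#' For every (before-cluster, after-cluster) square, the fraction of its
#' cells carrying the first batch label. Under a random pseudobatch split
#' every well-populated square should sit near 0.5; squares with fewer than
#' 10 cells are flagged as dimmed (too small to interpret).
#'
#' @param before,after cluster labels per cell.
#' @param batches batch label per cell (two levels; the first sorted level
#'   is the numerator batch).
#' @return list with `ratio` (matrix, NA for empty squares), `count`
#'   (matrix), `dimmed` (logical matrix, count < 10) and `batch` (numerator
#'   label). Rows/columns ordered as in [cluster_confusion()].
#' @export
batch_imbalance <- function(before, after, batches) {
  if (length(batches) != length(before))
    stop("batches must cover all cells", call. = FALSE)
  conf <- cluster_confusion(before, after)
  ref <- sort(unique(as.character(batches)))[1]
  num <- table(before = unclass(before)[batches == ref],
               after = unclass(after)[batches == ref])
  cnt <- matrix(0L, nrow(conf), ncol(conf), dimnames = dimnames(conf))
  ij <- expand.grid(r = rownames(num), c = colnames(num),
                    stringsAsFactors = FALSE)
  keep <- ij$r %in% rownames(cnt) & ij$c %in% colnames(cnt)
  ij <- ij[keep, , drop = FALSE]
  cnt[cbind(ij$r, ij$c)] <- as.integer(num[cbind(ij$r, ij$c)])
  ratio <- ifelse(conf > 0, cnt / conf, NA_real_)
  list(ratio = ratio, count = conf, dimmed = conf < 10, batch = ref)
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions via pair counting from
#' the contingency table: 1 for identical partitions, expectation 0 under
#' independent random labelings. When the permutation-model denominator is
#' zero (both partitions trivial), the value is 1 if the partitions are
#' identical as partitions, else 0.
#'
#' @param a,b cluster labels for the same cells.
#' @return the ARI, a real number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must cover the same cells", call. = FALSE)
  tab <- table(unclass(a), unclass(b))
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  denom <- max_index - expected
  if (denom == 0) {
    same <- all(apply(tab > 0, 1, sum) == 1) && all(apply(tab > 0, 2, sum) == 1)
    return(if (same) 1 else 0)
  }
  (sum_ij - expected) / denom
}
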