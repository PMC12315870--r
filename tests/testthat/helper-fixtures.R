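# Shared fixtures, generated in code. Sizes are kept small; the heavier
# simulations live in the individual tests that need them.

# Small two-type dataset with strong markers, used across modules.
small_sim <- function(n_cells = 400, n_genes = 300, n_cell_types = 2,
                      marker_genes_per_type = 30, marker_log2fc = 3,
                      seed = 5, ...) {
  simulate_counts(sim_config(n_cells = n_cells, n_genes = n_genes,
                             n_cell_types = n_cell_types,
                             marker_genes_per_type = marker_genes_per_type,
                             marker_log2fc = marker_log2fc, seed = seed, ...))
}

# Tiny hand-written count matrix for toy examples.
toy_counts <- function() {
  m <- matrix(c(2, 0, 2,
                1, 3, 0,
                0, 4, 5), nrow = 3, byrow = TRUE)
  count_matrix(m, cell_ids = c("a", "b", "c"), gene_ids = c("g1", "g2", "g3"))
}

# Independent brute-force rank-displacement oracle: full O(n^2 log n)
# sort-based computation, written without reusing package internals.
oracle_rank_displacement <- function(before, after, k) {
  n <- nrow(before)
  dmat <- function(x) as.matrix(dist(x))
  Db <- dmat(before); Da <- dmat(after)
  per_cell <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord_b <- others[order(Db[i, others], others)]
    ord_a <- others[order(Da[i, others], others)]
    rank_a <- match(ord_b[seq_len(k)], ord_a)
    per_cell[i] <- median(abs(seq_len(k) - rank_a))
  }
  list(per_cell = per_cell, median = median(per_cell))
}

# Independent pair-counting ARI oracle: enumerate all unordered pairs of
# elements and count agreements directly.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(if (n10 + n01 == 0) 1 else 0)
  (n11 - expected) / (maxi - expected)
}

# Independent numeric-ML hurdle oracle: direct optim() maximization of the
# same penalized two-part likelihood, at cell (not pattern) level.
oracle_hurdle_lrt <- function(values, covars, tested, ridge = 1e-3) {
  df <- as.data.frame(lapply(covars, factor))
  X_full <- model.matrix(as.formula(paste("~", paste(names(df), collapse = "+"))), df)
  keep <- setdiff(names(df), tested)
  X_null <- if (length(keep))
    model.matrix(as.formula(paste("~", paste(keep, collapse = "+"))), df)
  else model.matrix(~1, df)
  z <- as.numeric(values > 0)
  fit_logit <- function(X) {
    pen <- c(0, rep(ridge, ncol(X) - 1))
    nll <- function(b) {
      eta <- drop(X %*% b)
      -(sum(z * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
        - sum(pen * b^2))
    }
    o <- optim(numeric(ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    -o$value
  }
  stat <- 0; dfree <- 0
  if (any(z > 0) && any(z == 0)) {
    r1 <- qr(X_full)$rank; r0 <- qr(X_null)$rank
    if (r1 > r0) {
      stat <- stat + 2 * (fit_logit(X_full) - fit_logit(X_null))
      dfree <- dfree + (r1 - r0)
    }
  }
  expr <- which(z > 0)
  if (length(expr) >= 3) {
    Xf <- X_full[expr, , drop = FALSE]; Xn <- X_null[expr, , drop = FALSE]
    r1 <- qr(Xf)$rank; r0 <- qr(Xn)$rank
    if (r1 > r0 && length(expr) > r1) {
      rss <- function(X) sum(lm.fit(X, values[expr])$residuals^2)
      N <- length(expr)
      eps <- 1e-12 * (sum(values[expr]^2) + 1)
      stat <- stat + N * log((rss(Xn) + eps) / (rss(Xf) + eps))
      dfree <- dfree + (r1 - r0)
    }
  }
  list(stat = stat, df = dfree,
       p = if (dfree > 0) pchisq(stat, dfree, lower.tail = FALSE) else NA)
}
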