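# Two-part hurdle differential expression. The discrete part is a logistic
# model of the detection indicator (expression > 0) on the design
# covariates; the continuous part is a Gaussian linear model of the
# log-normalized value over detected cells only. A covariate is tested by a
# likelihood-ratio test whose statistic is the sum of the two parts'
# deviance differences, with degrees of freedom summed accordingly.
# The logistic part carries a small ridge penalty on non-intercept
# coefficients so perfectly separated genes keep finite statistics.

#' Differential-expression design
#'
#' Exactly the two supported model designs: expression on cluster alone, or
#' on batch plus cluster. The tested covariate is dropped from the null
#' model in the likelihood-ratio test. Only cells of the two named clusters
#' enter the model.
#'
#' @param covariates `"cluster"` or `c("batch", "cluster")`.
#' @param tested covariate whose effect is tested; must be in `covariates`.
#' @param clusters the two cluster labels compared (fold changes are
#'   `clusters[1]` minus `clusters[2]`).
#' @param counts_source `"corrected"` or
#'   `"uncorrected-with-corrected-clusters"` — which matrix the values come
#'   from (bookkeeping for the harness; the model itself is agnostic).
#' @return a list of class `de_design`.
#' @export
de_design <- function(covariates = "cluster", tested = "cluster", clusters,
                      counts_source = "corrected") {
  covariates <- match.arg(paste(sort(covariates), collapse = "+"),
                          c("cluster", "batch+cluster"))
  covariates <- if (covariates == "cluster") "cluster" else c("batch", "cluster")
  if (!tested %in% covariates)
    stop("tested covariate must be one of the design covariates", call. = FALSE)
  if (length(clusters) != 2)
    stop("exactly two clusters must be compared", call. = FALSE)
  counts_source <- match.arg(counts_source,
                             c("corrected",
                               "uncorrected-with-corrected-clusters"))
  structure(list(covariates = covariates, tested = tested,
                 clusters = clusters, counts_source = counts_source),
            class = "de_design")
}

# Ridge-penalized logistic fit on aggregated covariate patterns.
# X: P x q design, succ/tot: successes and trials per pattern.
# Returns the penalized log-likelihood at the optimum.
logistic_ridge_ll <- function(X, succ, tot, ridge) {
  q <- ncol(X)
  pen <- c(0, rep(ridge, q - 1))[seq_len(q)]   # intercept unpenalized
  # numerically stable log(1 + e^eta)
  log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)),
                                   log1p(exp(eta)))
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(succ * eta - tot * log1pexp(eta)) - sum(pen * b^2)
  }
  beta <- numeric(q)
  cur <- obj(beta)
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, succ - tot * p)) - 2 * pen * beta
    W <- tot * p * (1 - p)
    H <- crossprod(X, X * W) + diag(2 * pen + 1e-12, q)
    step <- tryCatch(solve(H, g), error = function(e) g / (max(diag(H)) + 1))
    val <- obj(beta + step)
    halv <- 0
    while ((!is.finite(val) || val < cur) && halv < 40) {
      step <- step / 2
      val <- obj(beta + step)
      halv <- halv + 1
    }
    if (!is.finite(val) || val < cur) break      # no improving step left
    beta <- beta + step
    improved <- val - cur
    cur <- val
    if (improved < 1e-10) break
  }
  cur
}

# Rank of a pattern-level design restricted to occupied patterns.
design_rank <- function(X, occupied) {
  if (!any(occupied)) return(0L)
  qr(X[occupied, , drop = FALSE])$rank
}

# Pattern-level machinery shared by all genes for one design: pattern id per
# cell and full/null design matrices at pattern level.
build_patterns <- function(covars, tested) {
  df <- as.data.frame(lapply(covars, factor))
  pat <- interaction(df, drop = TRUE, lex.order = TRUE)
  lev <- levels(pat)
  pdf <- unique(data.frame(df, pat = pat))
  pdf <- pdf[match(lev, pdf$pat), , drop = FALSE]
  form_full <- as.formula(paste("~", paste(names(covars), collapse = "+")))
  keep_null <- setdiff(names(covars), tested)
  form_null <- if (length(keep_null))
    as.formula(paste("~", paste(keep_null, collapse = "+"))) else ~1
  list(id = as.integer(pat),
       n_pat = length(lev),
       X_full = model.matrix(form_full, pdf),
       X_null = model.matrix(form_null, pdf))
}

# Hurdle LRTs for one gene from pattern-level sufficient statistics, with a
# per-gene cache so several tests sharing a model (e.g. the full
# batch+cluster fit tested against either covariate) fit it only once.
# designs: named list of pattern-level design matrices;
# tests: list of lists (full =, null =) naming entries of `designs`.
# tot: cells per pattern; s: detected per pattern; sy, sy2: sums of the
# value and squared value over detected cells per pattern.
hurdle_lrt_patterns_multi <- function(designs, tests, tot, s, sy, sy2, ridge) {
  n_expr <- sum(s)
  disc_on <- n_expr > 0 && n_expr < sum(tot)
  occ_d <- tot > 0
  occ_c <- s > 0
  mbar <- ifelse(occ_c, sy / pmax(s, 1), 0)
  ss_within <- sum(sy2) - sum(s * mbar^2)
  eps <- 1e-12 * (sum(sy2) + 1)
  ll_cache <- list(); rss_cache <- list(); rank_cache <- list()
  get_ll <- function(nm) {
    if (is.null(ll_cache[[nm]]))
      ll_cache[[nm]] <<- logistic_ridge_ll(designs[[nm]][occ_d, , drop = FALSE],
                                           s[occ_d], tot[occ_d], ridge)
    ll_cache[[nm]]
  }
  get_rss <- function(nm) {
    if (is.null(rss_cache[[nm]])) {
      fit <- lm.wfit(designs[[nm]][occ_c, , drop = FALSE], mbar[occ_c],
                     w = s[occ_c])
      rss_cache[[nm]] <<- ss_within + sum(s[occ_c] * fit$residuals^2)
    }
    rss_cache[[nm]]
  }
  get_rank <- function(nm, occ, tag) {
    key <- paste0(nm, tag)
    if (is.null(rank_cache[[key]]))
      rank_cache[[key]] <<- design_rank(designs[[nm]], occ)
    rank_cache[[key]]
  }
  lapply(tests, function(te) {
    stat <- 0; df <- 0L
    if (disc_on) {
      df_d <- get_rank(te$full, occ_d, "d") - get_rank(te$null, occ_d, "d")
      if (df_d > 0) {
        stat <- stat + max(0, 2 * (get_ll(te$full) - get_ll(te$null)))
        df <- df + df_d
      }
    }
    if (n_expr >= 3) {
      rk1 <- get_rank(te$full, occ_c, "c")
      df_c <- rk1 - get_rank(te$null, occ_c, "c")
      if (df_c > 0 && n_expr > rk1) {
        stat <- stat + max(0, n_expr * log((get_rss(te$null) + eps) /
                                             (get_rss(te$full) + eps)))
        df <- df + df_c
      }
    }
    if (df == 0L)
      return(list(stat = NA_real_, df = 0L, p = NA_real_, valid = FALSE))
    list(stat = stat, df = df,
         p = pchisq(stat, df, lower.tail = FALSE), valid = TRUE)
  })
}

# Single-test wrapper retained for hurdle_lrt().
hurdle_lrt_patterns <- function(pat, tot, s, sy, sy2, ridge) {
  hurdle_lrt_patterns_multi(list(full = pat$X_full, null = pat$X_null),
                            list(list(full = "full", null = "null")),
                            tot, s, sy, sy2, ridge)[[1]]
}

#' Hurdle likelihood-ratio test for one gene
#'
#' Fits the two-part hurdle model to one gene's normalized expression and
#' tests the chosen covariate by a likelihood-ratio test. If a part is
#' inestimable (detection indicator constant; fewer than 3 detected cells;
#' covariate confounded within the part) it contributes 0 with 0 degrees of
#' freedom; when both parts are inestimable the result is flagged invalid.
#'
#' @param values numeric vector of normalized expression (the cells of the
#'   two compared clusters).
#' @param covariates named list/data.frame of covariate values per cell
#'   (e.g. `list(cluster = ..., batch = ...)`).
#' @param tested name of the tested covariate.
#' @param ridge ridge penalty on non-intercept logistic coefficients.
#' @return list with `stat`, `df`, `p`, `valid`.
#' @export
hurdle_lrt <- function(values, covariates, tested = "cluster", ridge = 1e-3) {
  covariates <- as.list(covariates)
  if (!tested %in% names(covariates))
    stop("tested covariate missing from covariates", call. = FALSE)
  for (cv in covariates) if (length(cv) != length(values))
    stop("covariates must cover all cells", call. = FALSE)
  pat <- build_patterns(covariates, tested)
  z <- values > 0
  tot <- tabulate(pat$id, pat$n_pat)
  s <- tabulate(pat$id[z], pat$n_pat)
  sy <- drop(rowsum(values * z, pat$id, reorder = TRUE))
  sy2 <- drop(rowsum((values^2) * z, pat$id, reorder = TRUE))
  # rowsum drops absent patterns; realign
  align <- function(v) { out <- numeric(pat$n_pat); out[sort(unique(pat$id))] <- v; out }
  sy <- align(sy); sy2 <- align(sy2)
  hurdle_lrt_patterns(pat, tot, s, sy, sy2, ridge)
}

#' Log2 fold change between two cell groups
#'
#' Difference of group means of log2-scale expression (natural-log
#' normalized values divided by ln 2), zeros included.
#'
#' @param norm a `norm_matrix`.
#' @param cells_g1,cells_g2 cell indices (or ids) of the two groups.
#' @param gene gene index or id.
#' @return a single real; antisymmetric under group swap.
#' @export
log2_fold_change <- function(norm, cells_g1, cells_g2, gene) {
  if (!length(cells_g1) || !length(cells_g2))
    stop("both groups must be non-empty", call. = FALSE)
  g <- if (is.character(gene)) match(gene, norm$gene_ids) else as.integer(gene)
  if (is.na(g)) stop("unknown gene", call. = FALSE)
  i1 <- if (is.character(cells_g1)) match(cells_g1, norm$cell_ids) else cells_g1
  i2 <- if (is.character(cells_g2)) match(cells_g2, norm$cell_ids) else cells_g2
  (mean(norm$values[i1, g]) - mean(norm$values[i2, g])) / log(2)
}

#' Classify genes from p-value and fold change
#'
#' Volcano-plot classification: `up` / `down` for significant genes past the
#' fold-change threshold, `high-signal` for significant genes inside it,
#' `low-signal` otherwise.
#'
#' @param p p-value(s).
#' @param p_thresh significance threshold (Bonferroni-corrected alpha).
#' @param fc log2 fold change(s).
#' @param fc_thresh fold-change threshold (default 0.6).
#' @return character vector of classes.
#' @export
classify_de <- function(p, p_thresh, fc, fc_thresh = 0.6) {
  ifelse(is.na(p), "invalid",
         ifelse(p < p_thresh & fc > fc_thresh, "up",
                ifelse(p < p_thresh & fc < -fc_thresh, "down",
                       ifelse(p < p_thresh, "high-signal", "low-signal"))))
}

#' Differential expression between two clusters
#'
#' Runs the hurdle likelihood-ratio test per gene over the cells of the two
#' compared clusters only, computes log2 fold changes, applies Bonferroni
#' correction with the denominator equal to the number of genes returning a
#' valid model result, and classifies each gene.
#'
#' @param norm a `norm_matrix` (values the model is fitted to).
#' @param clustering cluster label per cell of `norm`.
#' @param design a [de_design()].
#' @param batches batch label per cell (required when the design includes
#'   batch).
#' @param genes gene indices to test (typically the HVG list); default all.
#' @param alpha family-wise error target before Bonferroni division.
#' @param fc_thresh volcano fold-change threshold.
#' @param ridge logistic ridge penalty.
#' @return a `data.frame` of class `de_result` with columns `gene`
#'   (index), `gene_id`, `stat`, `df`, `p`, `log2fc`, `significant`,
#'   `class`; attributes `alpha`, `n_tested`, `p_thresh`, `design`.
#' @export
run_de <- function(norm, clustering, design, batches = NULL, genes = NULL,
                   alpha = 0.05, fc_thresh = 0.6, ridge = 1e-3) {
  stopifnot(inherits(norm, "norm_matrix"), inherits(design, "de_design"))
  genes <- genes %||% seq_len(ncol(norm$values))
  cl <- as.character(unclass(clustering))
  pair <- as.character(design$clusters)
  for (lab in pair) if (!lab %in% cl)
    stop(sprintf("cluster '%s' of the compared pair is missing (marker matching failed upstream?)",
                 lab), call. = FALSE)
  cells <- which(cl %in% pair)
  covars <- list(cluster = factor(cl[cells], levels = pair))
  if ("batch" %in% design$covariates) {
    if (is.null(batches)) stop("design includes batch but no batch labels given",
                               call. = FALSE)
    covars$batch <- factor(as.character(batches)[cells])
  }
  pat <- build_patterns(covars, design$tested)
  z <- norm$values[cells, genes, drop = FALSE] > 0
  y <- norm$values[cells, genes, drop = FALSE] * z
  ind <- matrix(0, length(cells), pat$n_pat)
  ind[cbind(seq_along(cells), pat$id)] <- 1
  tot <- colSums(ind)
  S <- crossprod(ind, z)          # detected per pattern x gene
  SY <- crossprod(ind, y)
  SY2 <- crossprod(ind, y^2)
  res <- lapply(seq_along(genes), function(j) {
    hurdle_lrt_patterns(pat, tot, S[, j], SY[, j], SY2[, j], ridge)
  })
  g1 <- cells[covars$cluster == pair[1]]
  g2 <- cells[covars$cluster == pair[2]]
  fc <- (colMeans(norm$values[g1, genes, drop = FALSE]) -
           colMeans(norm$values[g2, genes, drop = FALSE])) / log(2)
  p <- vapply(res, `[[`, 0, "p")
  valid <- vapply(res, `[[`, TRUE, "valid")
  n_tested <- sum(valid)
  p_thresh <- if (n_tested > 0) alpha / n_tested else NA_real_
  out <- data.frame(gene = genes,
                    gene_id = norm$gene_ids[genes],
                    stat = vapply(res, `[[`, 0, "stat"),
                    df = vapply(res, `[[`, 0L, "df"),
                    p = p,
                    log2fc = fc,
                    significant = !is.na(p) & p < p_thresh,
                    class = classify_de(p, p_thresh, fc, fc_thresh),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_tested
  attr(out, "p_thresh") <- p_thresh
  attr(out, "design") <- design
  class(out) <- c("de_result", "data.frame")
  out
}

# All three standard tests (cluster | cluster-only design, cluster and
# batch | batch+cluster design) in one pass over the genes, sharing model
# fits. Returns a named list of de_result frames: cluster, bc_cluster,
# bc_batch.
run_de_designs <- function(norm, clustering, batches, pair, genes,
                           alpha = 0.05, fc_thresh = 0.6, ridge = 1e-3,
                           counts_source = "corrected") {
  cl <- as.character(unclass(clustering))
  pair <- as.character(pair)
  for (lab in pair) if (!lab %in% cl)
    stop(sprintf("cluster '%s' of the compared pair is missing", lab),
         call. = FALSE)
  cells <- which(cl %in% pair)
  covars <- list(cluster = factor(cl[cells], levels = pair),
                 batch = factor(as.character(batches)[cells]))
  df <- as.data.frame(covars)
  pat_f <- interaction(df, drop = TRUE, lex.order = TRUE)
  lev <- levels(pat_f)
  pdf <- unique(data.frame(df, pat = pat_f))
  pdf <- pdf[match(lev, pdf$pat), , drop = FALSE]
  designs <- list(null = model.matrix(~1, pdf),
                  c = model.matrix(~cluster, pdf),
                  b = model.matrix(~batch, pdf),
                  bc = model.matrix(~batch + cluster, pdf))
  tests <- list(cluster = list(full = "c", null = "null"),
                bc_cluster = list(full = "bc", null = "b"),
                bc_batch = list(full = "bc", null = "c"))
  id <- as.integer(pat_f)
  n_pat <- length(lev)
  zmat <- norm$values[cells, genes, drop = FALSE] > 0
  ymat <- norm$values[cells, genes, drop = FALSE] * zmat
  ind <- matrix(0, length(cells), n_pat)
  ind[cbind(seq_along(cells), id)] <- 1
  tot <- colSums(ind)
  S <- crossprod(ind, zmat)
  SY <- crossprod(ind, ymat)
  SY2 <- crossprod(ind, ymat^2)
  res <- lapply(seq_along(genes), function(j) {
    hurdle_lrt_patterns_multi(designs, tests, tot, S[, j], SY[, j], SY2[, j],
                              ridge)
  })
  g1 <- cells[covars$cluster == pair[1]]
  g2 <- cells[covars$cluster == pair[2]]
  fc <- (colMeans(norm$values[g1, genes, drop = FALSE]) -
           colMeans(norm$values[g2, genes, drop = FALSE])) / log(2)
  out <- list()
  for (tn in names(tests)) {
    p <- vapply(res, function(r) r[[tn]]$p, 0)
    valid <- vapply(res, function(r) r[[tn]]$valid, TRUE)
    n_tested <- sum(valid)
    p_thresh <- if (n_tested > 0) alpha / n_tested else NA_real_
    d <- data.frame(gene = genes, gene_id = norm$gene_ids[genes],
                    stat = vapply(res, function(r) r[[tn]]$stat, 0),
                    df = vapply(res, function(r) r[[tn]]$df, 0L),
                    p = p, log2fc = fc,
                    significant = !is.na(p) & p < p_thresh,
                    class = classify_de(p, p_thresh, fc, fc_thresh),
                    stringsAsFactors = FALSE)
    rownames(d) <- NULL
    attr(d, "alpha") <- alpha
    attr(d, "n_tested") <- n_tested
    attr(d, "p_thresh") <- p_thresh
    attr(d, "design") <- de_design(
      if (tn == "cluster") "cluster" else c("batch", "cluster"),
      if (tn == "bc_batch") "batch" else "cluster", pair, counts_source)
    class(d) <- c("de_result", "data.frame")
    out[[tn]] <- d
  }
  out
}

#' Overlap of significant gene sets
#'
#' Percentage of the genes significant after correction that were also
#' significant before: `100 * |S_after ∩ S_before| / |S_after|`. `NA` when
#' nothing is significant after correction.
#'
#' @param before,after `de_result` objects over the same gene universe.
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
de_overlap <- function(before, after) {
  if (!setequal(before$gene, after$gene))
    stop("gene universes differ", call. = FALSE)
  s_b <- before$gene[before$significant]
  s_a <- after$gene[after$significant]
  if (!length(s_a)) return(NA_real_)
  100 * length(intersect(s_a, s_b)) / length(s_a)
}

# One-sided (upregulated-in-group) Wilcoxon rank-sum p-values per gene and
# cluster, normal approximation with tie and continuity correction.
# One-sided so that a gene depleted in a cluster never ranks as its marker.
# Ranks and tie corrections are computed once per gene and shared across
# clusters. Returns list(p = genes x clusters matrix, log2fc = same shape).
marker_score_matrix <- function(values, clustering) {
  cl <- as.character(clustering)
  labs <- sort(unique(cl))
  N <- nrow(values); G <- ncol(values)
  R <- matrix(0, N, G)
  tie_term <- numeric(G)
  for (g in seq_len(G)) {
    x <- values[, g]
    R[, g] <- rank(x)
    ties <- rle(sort(x))$lengths
    tie_term[g] <- sum(ties^3 - ties)
  }
  grand <- colMeans(values)
  p <- fc <- matrix(NA_real_, G, length(labs),
                    dimnames = list(NULL, labs))
  for (b in labs) {
    ing <- cl == b
    n1 <- sum(ing); n2 <- N - n1
    if (n1 < 2 || n2 < 2) next
    U <- colSums(R[ing, , drop = FALSE]) - n1 * (n1 + 1) / 2
    v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U - 0.5 - n1 * n2 / 2) / sqrt(pmax(v, 1e-300))
    p[, b] <- ifelse(v <= 0, 1, pnorm(z, lower.tail = FALSE))
    m_in <- colMeans(values[ing, , drop = FALSE])
    # out-of-group mean from the grand mean
    m_out <- (grand * N - m_in * n1) / n2
    fc[, b] <- (m_in - m_out) / log(2)
  }
  list(p = p, log2fc = fc)
}

# Single-group convenience used by perturbation-target selection.
wilcox_marker_pvalues <- function(values, in_group) {
  cl <- ifelse(in_group, "in", "out")
  marker_score_matrix(values, cl)$p[, "in"]
}

#' Rank marker genes of one cluster
#'
#' One-vs-rest rank-sum test per gene; genes ordered by ascending p-value,
#' ties broken by larger log2 fold change, then gene index. Deterministic.
#'
#' @param norm a `norm_matrix`.
#' @param clustering cluster labels per cell.
#' @param cluster label of the cluster of interest (>= 2 cells).
#' @return `data.frame` with columns `gene`, `gene_id`, `p`, `log2fc` in
#'   rank order.
#' @export
rank_marker_genes <- function(norm, clustering, cluster) {
  cl <- as.character(unclass(clustering))
  ing <- cl == as.character(cluster)
  if (sum(ing) < 2)
    stop("cluster must contain at least two cells", call. = FALSE)
  sc <- marker_score_matrix(norm$values, ifelse(ing, "in", "out"))
  p <- sc$p[, "in"]
  fc <- sc$log2fc[, "in"]
  ord <- order(p, -fc, seq_along(p))
  data.frame(gene = ord, gene_id = norm$gene_ids[ord], p = p[ord],
             log2fc = fc[ord], row.names = NULL, stringsAsFactors = FALSE)
}

# Given a marker score matrix, find the cluster where gene g ranks best
# within the top_n of its one-vs-rest marker ordering; NULL when none.
identify_from_scores <- function(sc, g, top_n) {
  best <- NULL; best_rank <- Inf
  for (lab in colnames(sc$p)) {
    if (all(is.na(sc$p[, lab]))) next
    ord <- order(sc$p[, lab], -sc$log2fc[, lab], seq_len(nrow(sc$p)))
    rk <- match(g, ord)
    if (!is.na(rk) && rk <= top_n && rk < best_rank) {
      best <- lab; best_rank <- rk
    }
  }
  best
}

#' Identify a cluster by a marker gene
#'
#' Returns the cluster that carries the given gene as a top-`top_n` marker,
#' the way cell types are matched across corrected and uncorrected
#' clusterings. If several clusters qualify, the one where the marker ranks
#' best wins; if none does, an error of class `batchcal_marker_not_found` is
#' raised (the harness records such iterations as skipped).
#'
#' @param norm a `norm_matrix`.
#' @param clustering cluster labels per cell.
#' @param marker gene id (or index).
#' @param top_n how deep in the marker ranking to look (default 200).
#' @return the winning cluster label.
#' @export
identify_cluster_by_marker <- function(norm, clustering, marker, top_n = 200) {
  g <- if (is.character(marker)) match(marker, norm$gene_ids) else as.integer(marker)
  if (is.na(g) || g < 1 || g > length(norm$gene_ids))
    stop("marker gene not present in the matrix", call. = FALSE)
  sc <- marker_score_matrix(norm$values, as.character(unclass(clustering)))
  best <- identify_from_scores(sc, g, top_n)
  if (is.null(best)) {
    cond <- structure(class = c("batchcal_marker_not_found", "error",
                                "condition"),
                      list(message = sprintf(
                        "gene '%s' is not a top-%d marker of any cluster",
                        norm$gene_ids[g], top_n), call = NULL))
    stop(cond)
  }
  best
}
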