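# Pluggable corrector contract: a registry of correction methods keyed by id,
# each declaring which pipeline object it consumes (raw counts, normalized
# counts, embedding or k-NN graph) and returning a tagged correction result.

the_registry <- new.env(parent = emptyenv())

#' Register a batch-correction method
#'
#' Correctors plug into the calibration harness through this registry. The
#' callable receives the object matching `input_kind`, the batch labels and
#' an options list, and must return either a payload of the right type or a
#' ready-made [correction_result()].
#'
#' @param id unique corrector identifier.
#' @param input_kind one of `"raw-counts"`, `"normalized-counts"`,
#'   `"embedding"`, `"knn-graph"`.
#' @param fun function(object, batches, options) -> payload or
#'   [correction_result()].
#' @param overwrite allow re-registration of an existing id.
#' @return `id`, invisibly.
#' @export
register_corrector <- function(id, input_kind, fun, overwrite = FALSE) {
  input_kind <- match.arg(input_kind,
                          c("raw-counts", "normalized-counts", "embedding",
                            "knn-graph"))
  if (!overwrite && !is.null(the_registry[[id]]))
    stop(sprintf("corrector '%s' is already registered", id), call. = FALSE)
  the_registry[[id]] <- list(id = id, input_kind = input_kind, fun = fun)
  invisible(id)
}

#' Corrector specification
#'
#' @param id registered corrector id.
#' @param options named list of corrector options.
#' @return list of class `corrector_spec`.
#' @export
corrector_spec <- function(id, options = list()) {
  entry <- the_registry[[id]]
  if (is.null(entry))
    stop(sprintf("corrector '%s' is not registered", id), call. = FALSE)
  structure(list(id = id, input_kind = entry$input_kind, options = options),
            class = "corrector_spec")
}

#' @export
print.corrector_spec <- function(x, ...) {
  cat(sprintf("corrector '%s' (input: %s)\n", x$id, x$input_kind))
  invisible(x)
}

#' List registered correctors
#' @return character vector of corrector ids.
#' @export
list_correctors <- function() sort(ls(the_registry))

#' Tagged correction result
#'
#' @param tag one of `"counts"`, `"embedding"`, `"knn-graph"`.
#' @param payload the corrected object: a [count_matrix()] or `norm_matrix`
#'   for tag `"counts"`, an embedding matrix, or a `knn_graph`.
#' @param corrector_id id of the producing corrector.
#' @param options options echo.
#' @return list of class `correction_result`.
#' @export
correction_result <- function(tag, payload, corrector_id = NA_character_,
                              options = list()) {
  tag <- match.arg(tag, c("counts", "embedding", "knn-graph"))
  structure(list(tag = tag, payload = payload, corrector_id = corrector_id,
                 options = options),
            class = "correction_result")
}

# Validate a correction result against the input cell universe: matching
# cell set (reordered to input order when the corrector shuffled cells),
# finite values, and non-negative raw counts.
validate_correction <- function(result, cell_ids) {
  stopifnot(inherits(result, "correction_result"))
  p <- result$payload
  get_ids <- function() {
    if (inherits(p, "count_matrix") || inherits(p, "norm_matrix")) p$cell_ids
    else if (inherits(p, "knn_graph")) p$cell_ids
    else rownames(p)
  }
  ids <- get_ids()
  if (is.null(ids) || length(ids) != length(cell_ids) ||
      !setequal(ids, cell_ids))
    stop("corrector changed cell universe", call. = FALSE)
  if (!identical(ids, cell_ids)) {
    ord <- match(cell_ids, ids)
    if (inherits(p, "count_matrix") || inherits(p, "norm_matrix")) {
      p$values <- p$values[ord, , drop = FALSE]
      p$cell_ids <- cell_ids
      if (!is.null(p$cell_totals)) p$cell_totals <- p$cell_totals[ord]
    } else if (inherits(p, "knn_graph")) {
      stop("corrector returned a reordered k-NN graph; indices are ambiguous",
           call. = FALSE)
    } else {
      p <- p[ord, , drop = FALSE]
    }
    result$payload <- p
  }
  vals <- if (inherits(p, "count_matrix") || inherits(p, "norm_matrix"))
    p$values else if (inherits(p, "knn_graph")) p$dist else p
  if (any(!is.finite(vals)))
    stop("corrector returned non-finite values", call. = FALSE)
  if (result$tag == "counts" && inherits(p, "count_matrix") &&
      any(p$values < 0))
    stop("corrector returned negative counts", call. = FALSE)
  result
}

#' Apply a corrector to the appropriate pipeline object
#'
#' Dispatches the stage object matching the corrector's declared
#' `input_kind`, runs the registered callable, and validates the result
#' (finite values, unchanged cell universe; shuffled cell order is
#' re-aligned by id).
#'
#' @param spec a [corrector_spec()].
#' @param counts raw [count_matrix()].
#' @param norm [normalize_log()] result.
#' @param embedding PCA embedding.
#' @param graph [knn_graph()].
#' @param batches batch label per cell.
#' @return a validated [correction_result()].
#' @export
apply_corrector <- function(spec, counts, norm = NULL, embedding = NULL,
                            graph = NULL, batches = NULL) {
  stopifnot(inherits(spec, "corrector_spec"))
  entry <- the_registry[[spec$id]]
  obj <- switch(entry$input_kind,
                "raw-counts" = counts,
                "normalized-counts" = norm,
                "embedding" = embedding,
                "knn-graph" = graph)
  if (is.null(obj))
    stop(sprintf("corrector '%s' needs a %s object", spec$id,
                 entry$input_kind), call. = FALSE)
  res <- entry$fun(obj, batches, spec$options)
  if (!inherits(res, "correction_result")) {
    tag <- switch(entry$input_kind,
                  "raw-counts" = "counts", "normalized-counts" = "counts",
                  "embedding" = "embedding", "knn-graph" = "knn-graph")
    res <- correction_result(tag, res, spec$id, spec$options)
  }
  res$corrector_id <- spec$id
  validate_correction(res, counts$cell_ids)
}

#' Identity corrector
#'
#' Returns its input unchanged. This is the fixed point of the calibration
#' null: a perfectly calibrated correction of data without batch effects
#' should be indistinguishable from doing nothing.
#'
#' @param object any pipeline object.
#' @param batches ignored.
#' @param options ignored.
#' @return the input, tagged by its type.
#' @export
identity_corrector <- function(object, batches = NULL, options = list()) {
  tag <- if (inherits(object, "count_matrix") || inherits(object, "norm_matrix"))
    "counts" else if (inherits(object, "knn_graph")) "knn-graph" else "embedding"
  correction_result(tag, object, "identity", options)
}

#' Location-scale reference corrector
#'
#' Per gene and batch, standardizes the normalized expression to the pooled
#' mean and pooled standard deviation:
#' `x -> (x - m_b) / s_b * s_pool + m_pool`. Genes with zero within-batch
#' variance are mean-shifted only. A deliberately plain linear baseline —
#' no empirical-Bayes shrinkage — used to exercise the harness with a
#' corrector that actually changes the data.
#'
#' @param norm a `norm_matrix`.
#' @param batches batch label per cell (two levels, each with >= 2 cells).
#' @param options ignored.
#' @return a [correction_result()] with tag `"counts"` (normalized scale).
#' @export
location_scale_corrector <- function(norm, batches, options = list()) {
  stopifnot(inherits(norm, "norm_matrix"))
  labs <- unique(batches)
  for (b in labs) if (sum(batches == b) < 2)
    stop(sprintf("batch '%s' has fewer than two cells", b), call. = FALSE)
  v <- norm$values
  m_pool <- colMeans(v)
  s_pool <- apply(v, 2, sd)
  out <- v
  for (b in labs) {
    ix <- batches == b
    sub <- v[ix, , drop = FALSE]
    m_b <- colMeans(sub)
    s_b <- apply(sub, 2, sd)
    scale_fac <- ifelse(s_b > 0, s_pool / s_b, 1)
    out[ix, ] <- sweep(sweep(sub, 2, m_b), 2, scale_fac, `*`) +
      rep(m_pool, each = sum(ix))
  }
  res <- norm
  res$values <- out
  correction_result("counts", res, "location_scale", options)
}

#' Oracle inverse corrector
#'
#' Exactly undoes a deterministic (exact-mode) injected batch effect: the
#' normalized values are mapped back to the count scale, the affected
#' (batch, gene) entries are divided by the injection factor, and the matrix
#' is renormalized. Reproduces the unperturbed normalized matrix up to
#' floating point. A test oracle, not a realistic method; it requires the
#' `injected_effect` record and exact (non-stochastic) injection.
#'
#' @param norm a `norm_matrix` computed from exact-mode perturbed counts.
#' @param batches batch label per cell.
#' @param options list with element `injected_effect` (from the attribute
#'   set by [inject_batch_effect()]).
#' @return a [correction_result()] with tag `"counts"` (normalized scale).
#' @export
oracle_inverse_corrector <- function(norm, batches, options = list()) {
  stopifnot(inherits(norm, "norm_matrix"))
  eff <- options$injected_effect
  if (is.null(eff)) stop("missing injected_effect record", call. = FALSE)
  if (!identical(eff$mode, "exact"))
    stop("oracle inverse requires exact-mode injection", call. = FALSE)
  # back to count scale using the stored (perturbed) totals
  cnt <- expm1(norm$values) * (norm$cell_totals / norm$target_sum)
  cells <- which(batches == eff$batch)
  if (length(eff$genes) && length(cells))
    cnt[cells, eff$genes] <- cnt[cells, eff$genes, drop = FALSE] / eff$factor
  cnt[cnt < 0] <- 0
  tot <- rowSums(cnt)
  res <- norm
  res$values <- log1p(cnt * (norm$target_sum / tot))
  res$cell_totals <- tot
  correction_result("counts", res, "oracle_inverse", options)
}

register_builtin_correctors <- function() {
  if (is.null(the_registry[["identity"]]))
    register_corrector("identity", "raw-counts", identity_corrector)
  if (is.null(the_registry[["location_scale"]]))
    register_corrector("location_scale", "normalized-counts",
                       location_scale_corrector)
  if (is.null(the_registry[["oracle_inverse"]]))
    register_corrector("oracle_inverse", "normalized-counts",
                       oracle_inverse_corrector)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_correctors()
}
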