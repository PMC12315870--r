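#' UMI count matrix container
#'
#' A light container for a cells x genes UMI count matrix with unique cell
#' and gene identifiers. Values are non-negative; raw UMI data are integers,
#' but deterministic (exact-mode) perturbations may produce fractional
#' values, which the container permits.
#'
#' @param values numeric matrix, cells in rows, genes in columns,
#'   non-negative.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames or `cell1..cellN`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing colnames or `gene1..geneG`.
#' @return An object of class `count_matrix`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  cell_ids <- cell_ids %||% rownames(values) %||% paste0("cell", seq_len(nrow(values)))
  gene_ids <- gene_ids %||% colnames(values) %||% paste0("gene", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values) || anyDuplicated(cell_ids)) {
    stop("cell_ids must be unique and match the number of rows", call. = FALSE)
  }
  if (length(gene_ids) != ncol(values) || anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique and match the number of columns", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("UMI count matrix: %d cells x %d genes, %.1f%% non-zero\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Write a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx` (cells x genes by default, 1-based indices),
#' `barcodes.tsv` (one cell barcode per line) and `genes.tsv`
#' (gene id TAB gene name). When ground truth is supplied, also writes
#' `cell_types.tsv` (cell TAB type) and `marker_genes.tsv`
#' (type TAB comma-separated 1-based marker gene indices).
#'
#' @param counts a [count_matrix()].
#' @param dir output directory, created if missing.
#' @param truth optional ground-truth list from [simulate_counts()].
#' @param genes_as_rows write the matrix transposed (genes x cells), the 10x
#'   on-disk orientation. Default `FALSE` (cells x genes).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, truth = NULL, genes_as_rows = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(counts$values, sparse = TRUE)
  if (genes_as_rows) m <- Matrix::t(m)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = counts$gene_ids, name = counts$gene_ids),
              file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    write.table(data.frame(cell = counts$cell_ids, type = truth$cell_type_of_cell),
                file.path(dir, "cell_types.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    mk <- vapply(truth$marker_genes_of_type, function(ix) paste(ix, collapse = ","), "")
    write.table(data.frame(type = names(truth$marker_genes_of_type), markers = mk),
                file.path(dir, "marker_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix from a Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `genes.tsv` as written by
#' [write_counts_mtx()] (or the 10x convention with genes as rows, see
#' `genes_as_rows`).
#'
#' @param dir directory containing the triplet.
#' @param genes_as_rows whether the stored matrix is genes x cells.
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(dir, genes_as_rows = FALSE) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (genes_as_rows) m <- Matrix::t(m)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- read.table(file.path(dir, "genes.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  count_matrix(as.matrix(m), cell_ids = barcodes, gene_ids = genes[[1]])
}

#' Read a dense TSV count matrix
#'
#' Toy-input convenience: a TSV with gene ids as column names and cell ids
#' as the first column.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                  check.names = FALSE)
  count_matrix(as.matrix(d), cell_ids = rownames(d), gene_ids = colnames(d))
}
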