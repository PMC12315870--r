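# Report persistence: machine-readable JSON plus flat TSV tables.

#' Write a calibration report to disk
#'
#' Emits `report.json` (corrector, configuration, per-iteration scalar
#' metrics, skip reasons, medians), `metrics.tsv` (one row per iteration),
#' and for the first successful iteration the matched confusion matrix
#' (`confusion.tsv`), batch-ratio table (`batch_ratio.tsv`) and, when the
#' DE stage ran, the volcano before/after table (`volcano.tsv`).
#'
#' @param report a `calibration_report` from [calibrate()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_calibration_report <- function(report, dir) {
  stopifnot(inherits(report, "calibration_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iters <- lapply(report$iterations, function(it) {
    list(seed = it$seed, status = it$status,
         metrics = as.list(it$metrics),
         skipped = as.list(it$skipped),
         error = it$error %||% NULL)
  })
  cfg <- report$config
  cfg$de_markers <- as.list(cfg$de_markers)
  obj <- list(corrector = report$corrector,
              corrector_options = report$corrector_options,
              n_iterations = report$n_iterations,
              n_failed = report$n_failed,
              base_seed = report$base_seed,
              fingerprint = report$fingerprint,
              config = cfg,
              medians = as.list(report$medians),
              iterations = iters)
  jsonlite::write_json(obj, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  write.table(as.data.frame(report), file.path(dir, "metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- which(vapply(report$iterations, function(i) i$status == "ok", TRUE))
  if (length(ok)) {
    det <- report$iterations[[ok[1]]]$details
    if (!is.null(det$confusion))
      write.table(det$confusion, file.path(dir, "confusion.tsv"),
                  sep = "\t", quote = FALSE)
    if (!is.null(det$imbalance))
      write.table(det$imbalance$ratio, file.path(dir, "batch_ratio.tsv"),
                  sep = "\t", quote = FALSE)
    if (!is.null(det$volcano))
      write.table(det$volcano, file.path(dir, "volcano.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(det$rank_displacement))
      write.table(data.frame(cell_id = names(det$rank_displacement$per_cell),
                             value = det$rank_displacement$per_cell),
                  file.path(dir, "rank_displacement.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read back a written calibration report
#'
#' @param dir directory written by [write_calibration_report()].
#' @return the parsed `report.json` as a list.
#' @export
read_calibration_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}

#' Compare calibration reports side by side
#'
#' Builds a table of median metrics with one column per corrector. Reports
#' carrying different dataset fingerprints are still compared, with a
#' warning.
#'
#' @param reports list of `calibration_report` objects, or of directories
#'   written by [write_calibration_report()].
#' @return `data.frame`, metrics in rows, one column per report.
#' @export
compare_reports <- function(reports) {
  if (inherits(reports, "calibration_report")) reports <- list(reports)
  loaded <- lapply(reports, function(r) {
    if (inherits(r, "calibration_report"))
      list(corrector = r$corrector, medians = as.list(r$medians),
           fingerprint = r$fingerprint)
    else read_calibration_report(r)
  })
  fps <- vapply(loaded, function(r) r$fingerprint %||% "", "")
  if (length(unique(fps)) > 1)
    warning("reports come from different datasets; comparison may be meaningless")
  metric_names <- unique(unlist(lapply(loaded, function(r) names(r$medians))))
  out <- data.frame(metric = metric_names, stringsAsFactors = FALSE)
  for (r in loaded) {
    v <- unlist(r$medians)[metric_names]
    out[[r$corrector]] <- as.numeric(v)
  }
  out
}
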