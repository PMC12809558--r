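#' Read a spatial transcriptomics dataset bundle
#'
#' A bundle directory holds `matrix.mtx` (MatrixMarket sparse counts),
#' `genes.tsv`, `barcodes.tsv`, `coords.csv` (columns `cell_id,x,y`), an
#' optional `labels.csv` (columns `cell_id,label`) and a one-line YAML
#' `manifest.yaml` declaring the on-disk matrix orientation
#' (`orientation: genes_x_cells` or `cells_x_genes`). When the manifest is
#' absent the 10x convention (gene-major) is assumed. The in-memory
#' canonical orientation is always cells x genes, rows ordered as in
#' `barcodes.tsv`; coordinates and labels are joined by exact `cell_id`
#' match.
#'
#' @param bundle_dir path to the bundle directory.
#' @return A [spatial_dataset].
#' @export
read_spatial_dataset <- function(bundle_dir) {
  need <- file.path(bundle_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv", "coords.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stopf("bundle is missing: %s", paste(basename(missing), collapse = ", "))

  m <- Matrix::readMM(file.path(bundle_dir, "matrix.mtx"))
  genes <- readLines(file.path(bundle_dir, "genes.tsv"))
  genes <- sub("\t.*$", "", genes[nzchar(genes)])
  barcodes <- readLines(file.path(bundle_dir, "barcodes.tsv"))
  barcodes <- barcodes[nzchar(barcodes)]

  manifest_path <- file.path(bundle_dir, "manifest.yaml")
  orientation <- "genes_x_cells"
  platform_tag <- "bundle"
  if (file.exists(manifest_path)) {
    man <- yaml::read_yaml(manifest_path)
    orientation <- man$orientation %||% orientation
    platform_tag <- man$platform_tag %||% platform_tag
  }
  if (!orientation %in% c("genes_x_cells", "cells_x_genes"))
    stopf("unknown manifest orientation '%s'", orientation)
  if (orientation == "genes_x_cells") m <- Matrix::t(m)
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes))
    stopf("matrix is %d x %d after orientation but bundle lists %d barcodes and %d genes",
          nrow(m), ncol(m), length(barcodes), length(genes))
  if (any(m@x != round(m@x))) stopf("matrix.mtx contains non-integer count entries")
  if (anyDuplicated(barcodes)) stopf("duplicate cell ids in barcodes.tsv")
  if (anyDuplicated(genes)) stopf("duplicate gene ids in genes.tsv")

  coords_df <- utils::read.csv(file.path(bundle_dir, "coords.csv"),
                               colClasses = c(cell_id = "character"))
  check_id_match(barcodes, coords_df$cell_id, "coords.csv")
  coords <- as.matrix(coords_df[match(barcodes, coords_df$cell_id), c("x", "y")])

  labels <- NULL
  labels_path <- file.path(bundle_dir, "labels.csv")
  if (file.exists(labels_path)) {
    lab_df <- utils::read.csv(labels_path, colClasses = "character")
    check_id_match(barcodes, lab_df$cell_id, "labels.csv")
    labels <- lab_df$label[match(barcodes, lab_df$cell_id)]
  }

  spatial_dataset(m, coords, barcodes, genes, truth_labels = labels,
                  platform_tag = platform_tag)
}

check_id_match <- function(expected, got, file) {
  miss <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  if (length(miss) || length(extra))
    stopf("cell_id mismatch in %s: %d missing (first: %s), %d unexpected (first: %s)",
          file, length(miss), paste(utils::head(miss, 10), collapse = ","),
          length(extra), paste(utils::head(extra, 10), collapse = ","))
  if (anyDuplicated(got)) stopf("duplicate cell ids in %s", file)
}

#' Write a spatial transcriptomics dataset bundle
#'
#' Serializes a dataset so that [read_spatial_dataset()] reproduces it
#' exactly (counts bit-exact, coordinates to at least 12 significant
#' digits). The matrix is written gene-major with a manifest declaring it.
#'
#' @param ds a [spatial_dataset].
#' @param bundle_dir output directory (created if needed).
#' @export
write_spatial_dataset <- function(ds, bundle_dir) {
  if (length(ds$cell_ids) == 0 || length(ds$gene_ids) == 0)
    stopf("refusing to serialize a degenerate bundle with 0 cells or 0 genes")
  dir.create(bundle_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(bundle_dir)) stopf("cannot create %s", bundle_dir)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(bundle_dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(bundle_dir, "genes.tsv"))
  writeLines(ds$cell_ids, file.path(bundle_dir, "barcodes.tsv"))
  coords_df <- data.frame(cell_id = ds$cell_ids,
                          x = format(ds$coords[, 1], digits = 15, trim = TRUE),
                          y = format(ds$coords[, 2], digits = 15, trim = TRUE))
  utils::write.csv(coords_df, file.path(bundle_dir, "coords.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(ds$truth_labels))
    utils::write.csv(data.frame(cell_id = ds$cell_ids, label = ds$truth_labels),
                     file.path(bundle_dir, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(orientation = "genes_x_cells",
                        platform_tag = ds$platform_tag),
                   file.path(bundle_dir, "manifest.yaml"))
  invisible(NULL)
}

metric_names <- c("AMI", "WF1", "PGAMMA", "SC", "MSAMI")
condition_names <- c("HV", "SV", "CONCAT", "RANDOM")

#' Validate a metric report table
#'
#' A metric report is a data.frame with columns
#' `dataset_id, condition, method, metric, value`: one row per
#' (dataset, condition, method, metric). AMI, WF1, SC and MSAMI lie in
#' \[0,1\]; PGAMMA in \[-1,1\].
#'
#' @param report data.frame to validate.
#' @return the report, invisibly, or an error.
#' @export
validate_metric_report <- function(report) {
  cols <- c("dataset_id", "condition", "method", "metric", "value")
  if (!all(cols %in% names(report)))
    stopf("metric report must have columns %s", paste(cols, collapse = ","))
  if (!all(report$metric %in% metric_names))
    stopf("unknown metric name(s): %s",
          paste(setdiff(unique(report$metric), metric_names), collapse = ","))
  if (!all(report$condition %in% condition_names))
    stopf("unknown condition(s): %s",
          paste(setdiff(unique(report$condition), condition_names), collapse = ","))
  key <- paste(report$dataset_id, report$condition, report$method, report$metric)
  if (anyDuplicated(key))
    stopf("duplicate metric report rows for key(s): %s",
          paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  unit <- report$metric %in% c("AMI", "WF1", "SC", "MSAMI")
  if (any(report$value[unit] < 0 | report$value[unit] > 1, na.rm = TRUE))
    stopf("AMI/WF1/SC/MSAMI values must lie in [0,1]")
  if (any(abs(report$value[report$metric == "PGAMMA"]) > 1, na.rm = TRUE))
    stopf("PGAMMA values must lie in [-1,1]")
  invisible(report)
}

#' Write / read a metric report CSV
#'
#' Fixed header `dataset_id,condition,method,metric,value`; values survive a
#' round-trip to at least 12 significant digits.
#'
#' @param report a valid metric report data.frame.
#' @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  validate_metric_report(report)
  out <- report[, c("dataset_id", "condition", "method", "metric", "value")]
  out$value <- format(out$value, digits = 15, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  rep <- utils::read.csv(path, colClasses = c(dataset_id = "character",
                                              condition = "character",
                                              method = "character",
                                              metric = "character",
                                              value = "numeric"))
  validate_metric_report(rep)
  rep
}
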