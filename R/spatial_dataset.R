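#' Construct a spatial transcriptomics dataset
#'
#' The container every pipeline stage consumes and produces: a cells x genes
#' UMI count matrix, per-cell spatial coordinates, unique cell and gene
#' identifiers, and (optionally) ground-truth cell-type labels.
#'
#' @param counts cells x genes non-negative integer matrix (base matrix or
#'   a sparse [Matrix::Matrix]). Rows are cells.
#' @param coords cells x 2 numeric matrix of spatial positions (same length
#'   unit on both axes).
#' @param cell_ids character vector of unique cell identifiers.
#' @param gene_ids character vector of unique gene identifiers.
#' @param truth_labels optional per-cell categorical labels with at least
#'   two distinct values.
#' @param platform_tag free-form string recording the data source.
#'
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, cell_ids, gene_ids,
                            truth_labels = NULL, platform_tag = "synthetic") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stopf("counts is %d x %d but there are %d cell ids and %d gene ids",
          nrow(counts), ncol(counts), length(cell_ids), length(gene_ids))
  if (nrow(coords) != length(cell_ids) || ncol(coords) != 2)
    stopf("coords must be %d x 2", length(cell_ids))
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stopf("counts must be non-negative integers")
  if (!is.null(truth_labels)) {
    truth_labels <- as.character(truth_labels)
    if (length(truth_labels) != length(cell_ids))
      stopf("truth_labels length %d != number of cells %d",
            length(truth_labels), length(cell_ids))
    if (length(unique(truth_labels)) < 2)
      stopf("truth_labels must have at least 2 distinct values")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  rownames(coords) <- cell_ids
  colnames(coords) <- c("x", "y")
  structure(list(counts = counts, coords = coords, cell_ids = cell_ids,
                 gene_ids = gene_ids, truth_labels = truth_labels,
                 platform_tag = platform_tag),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d cells x %d genes (%s)\n",
              length(x$cell_ids), length(x$gene_ids), x$platform_tag))
  if (!is.null(x$truth_labels))
    cat("  truth labels:", paste(utils::head(sort(unique(x$truth_labels)), 8),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

# Subset a dataset by cell and/or gene index, preserving order.
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  cells <- cells %||% seq_along(ds$cell_ids)
  genes <- genes %||% seq_along(ds$gene_ids)
  spatial_dataset(ds$counts[cells, genes, drop = FALSE],
                  ds$coords[cells, , drop = FALSE],
                  ds$cell_ids[cells], ds$gene_ids[genes],
                  truth_labels = if (!is.null(ds$truth_labels)) ds$truth_labels[cells],
                  platform_tag = ds$platform_tag)
}
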