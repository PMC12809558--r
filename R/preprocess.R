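#' Remove statistical-outlier genes and cells
#'
#' Computes per-gene and per-cell mean expression and removes entries whose
#' mean falls outside the Tukey fences `[Q1 - k_iqr*IQR, Q3 + k_iqr*IQR]`
#' of the respective distribution. Genes are filtered first, then cells on
#' the gene-filtered matrix; survivor order is preserved. Fences are
#' computed on the log of the means by default, so that low-expression
#' outliers are detectable (on the raw scale the lower fence is negative
#' whenever the IQR is comparable to Q1, and low outliers can never
#' trigger); genes or cells with an all-zero mean are always treated as
#' low outliers under the log rule.
#'
#' @param ds a [spatial_dataset].
#' @param k_iqr fence multiplier (Tukey's rule uses 1.5; a permissive 3 is
#'   the default so only gross outliers are removed).
#' @param log_scale compute fences on log-means (default) or raw means.
#' @return the filtered [spatial_dataset].
#' @export
filter_outliers <- function(ds, k_iqr = 3.0, log_scale = TRUE) {
  if (length(ds$gene_ids) < 4 || length(ds$cell_ids) < 4)
    stopf("need at least 4 genes and 4 cells to estimate outlier fences")
  keep_by_fence <- function(means) {
    v <- if (log_scale) suppressWarnings(log(means)) else means
    fin <- is.finite(v)
    if (!any(fin)) return(rep(FALSE, length(v)))
    q <- stats::quantile(v[fin], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    fin & v >= q[1] - k_iqr * iqr & v <= q[2] + k_iqr * iqr
  }
  gene_means <- Matrix::colMeans(ds$counts)
  keep_g <- keep_by_fence(gene_means)
  if (!any(keep_g)) stopf("outlier filter removed all genes")
  sub <- subset_dataset(ds, genes = which(keep_g))
  cell_means <- Matrix::rowMeans(sub$counts)
  keep_c <- keep_by_fence(cell_means)
  if (!any(keep_c)) stopf("outlier filter removed all cells")
  subset_dataset(sub, cells = which(keep_c))
}

#' Remove rare cell types
#'
#' Drops all cells whose ground-truth type frequency (computed on the
#' input) is strictly below `min_frac`; at least two types must remain.
#'
#' @param ds a [spatial_dataset] with `truth_labels`.
#' @param min_frac minimum type frequency (strict `<` comparison: a type at
#'   exactly `min_frac` is kept).
#' @return the filtered [spatial_dataset].
#' @export
filter_rare_types <- function(ds, min_frac = 0.05) {
  if (is.null(ds$truth_labels))
    stopf("filter_rare_types requires ground-truth labels")
  freq <- table(ds$truth_labels) / length(ds$truth_labels)
  keep_types <- names(freq)[freq >= min_frac]
  if (length(keep_types) < 2)
    stopf("fewer than 2 cell types remain after removing types below %.1f%%",
          100 * min_frac)
  subset_dataset(ds, cells = which(ds$truth_labels %in% keep_types))
}

new_normalized_matrix <- function(values, kind, params) {
  structure(list(values = values, kind = kind, params = params),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d x %d, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Log-normalize a count matrix
#'
#' Counts are multiplied by `rescale_factor`, each cell is scaled to a
#' total of `target_sum`, and values are transformed as `ln(1 + scaled)`.
#'
#' @param counts cells x genes count matrix (or a [spatial_dataset]).
#' @param rescale_factor global multiplier applied before per-cell scaling
#'   (1000 is conventional for MERFISH panels; it cancels in the per-cell
#'   normalization and matters only if per-cell scaling is skipped).
#' @param target_sum per-cell total after scaling.
#' @return a `normalized_matrix` of kind `LOGNORM`.
#' @export
lognormalize <- function(counts, rescale_factor = 1.0, target_sum = 1e4) {
  if (inherits(counts, "spatial_dataset")) counts <- counts$counts
  m <- as_dense(counts)
  tot <- rowSums(m) * rescale_factor
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    stopf("all-zero cell(s): %s",
          paste(utils::head(rownames(m)[bad] %||% bad, 10), collapse = ","))
  }
  scaled <- m * rescale_factor * (target_sum / tot)
  new_normalized_matrix(log1p(scaled), "LOGNORM",
                        list(rescale_factor = rescale_factor,
                             target_sum = target_sum, pseudocount = 1))
}

#' Analytic Pearson residual normalization
#'
#' Residuals of the depth-by-gene independence model:
#' `r = (x - mu) / sqrt(mu + mu^2 / theta)` with
#' `mu = rowsum * colsum / grandsum`, clipped to `±clip`
#' (default `sqrt(n_cells)`). Matrices whose entries equal their
#' independence expectation give identically zero residuals.
#'
#' @param counts cells x genes count matrix (or a [spatial_dataset]).
#' @param theta assumed negative binomial dispersion of the null model.
#' @param clip clipping bound; `NULL` for the `sqrt(n_cells)` default.
#' @return a `normalized_matrix` of kind `PEARSON_RESIDUAL`.
#' @export
pearson_residuals <- function(counts, theta = 100, clip = NULL) {
  if (inherits(counts, "spatial_dataset")) counts <- counts$counts
  m <- as_dense(counts)
  rs <- rowSums(m); cs <- colSums(m); gt <- sum(m)
  if (gt <= 0) stopf("grand total of counts must be > 0")
  if (any(rs == 0)) stopf("all-zero cell row(s): %s",
                          paste(utils::head(which(rs == 0), 10), collapse = ","))
  if (any(cs == 0)) stopf("all-zero gene column(s): %s",
                          paste(utils::head(which(cs == 0), 10), collapse = ","))
  clip <- clip %||% sqrt(nrow(m))
  mu <- outer(rs, cs) / gt
  r <- (m - mu) / sqrt(mu + mu^2 / theta)
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  new_normalized_matrix(r, "PEARSON_RESIDUAL", list(theta = theta, clip = clip))
}

#' Per-gene variance of a normalized matrix
#'
#' Sample variance (denominator `n - 1`) of each gene column; the statistic
#' behind the residual-variance HV-gene rule.
#'
#' @param norm a `normalized_matrix` (or plain matrix).
#' @return named numeric vector of per-gene variances.
#' @export
gene_variance <- function(norm) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  n <- nrow(v)
  mu <- colMeans(v)
  (colSums(v^2) - n * mu^2) / (n - 1)
}
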