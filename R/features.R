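#' Gene selection container
#'
#' An ordered set of gene ids with the per-gene statistic that selected
#' them, a method tag and a threshold level.
#'
#' @param gene_ids ordered unique gene ids.
#' @param statistic per-gene statistic aligned with `gene_ids` (residual
#'   variance, CV excess, or permutation p-value).
#' @param method one of `HVG_RESID`, `HVG_LOESS`, `SVG_MORAN`, `CONCAT`,
#'   `RANDOM`.
#' @param level one of `LOW`, `MED`, `HIGH`, `NA`.
#' @return a `gene_selection` object.
#' @export
gene_selection <- function(gene_ids, statistic, method, level = NA_character_) {
  if (!length(gene_ids)) stopf("empty gene selection")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids in selection")
  if (length(statistic) != length(gene_ids))
    stopf("statistic not aligned with gene_ids")
  structure(list(gene_ids = as.character(gene_ids),
                 statistic = as.numeric(statistic),
                 method = method, level = level),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %s/%s: %d genes\n", x$method, x$level,
              length(x$gene_ids)))
  invisible(x)
}

#' @export
length.gene_selection <- function(x) length(x$gene_ids)

level_prob <- c(LOW = 0.50, MED = 0.70, HIGH = 0.90)

check_level <- function(level) {
  level <- toupper(level)
  if (!level %in% c("LOW", "MED", "HIGH")) stopf("level must be LOW, MED or HIGH")
  level
}

#' Select HV genes by Pearson residual variance
#'
#' Candidate genes have per-gene residual variance strictly greater than 1
#' (under the analytic residual null model, uninformative genes have
#' variance near 1). Within the candidates, the level keeps genes at or
#' above the 50th (`LOW`), 70th (`MED`) or 90th (`HIGH`)
#' linear-interpolation percentile of the candidate variance distribution.
#'
#' @param residuals a `normalized_matrix` of kind `PEARSON_RESIDUAL` with
#'   gene columns named.
#' @param level threshold level.
#' @return a `gene_selection` (method `HVG_RESID`), variance-descending.
#' @export
select_hvg_residual_variance <- function(residuals, level = "LOW") {
  level <- check_level(level)
  v <- gene_variance(residuals)
  cand <- v[v > 1]
  if (!length(cand)) stopf("no HV genes: no gene has residual variance > 1")
  cut <- stats::quantile(cand, level_prob[[level]], names = FALSE, type = 7)
  keep <- cand[cand >= cut]
  keep <- sort(keep, decreasing = TRUE)
  gene_selection(names(keep), unname(keep), "HVG_RESID", level)
}

#' Select HV genes by LOESS coefficient-of-variation excess
#'
#' Fits a LOESS curve of the per-gene coefficient of variation (sd/mean of
#' the log-normalized expression) against log mean expression; the
#' statistic is the observed CV minus the fitted CV. Candidates have
#' positive excess; the level keeps candidates at or above the
#' corresponding percentile of the excess distribution.
#'
#' @param lognorm a `normalized_matrix` of kind `LOGNORM`.
#' @param level threshold level.
#' @param span LOESS span.
#' @return a `gene_selection` (method `HVG_LOESS`), excess-descending.
#' @export
select_hvg_loess_cv <- function(lognorm, level = "LOW", span = 0.3) {
  level <- check_level(level)
  v <- if (inherits(lognorm, "normalized_matrix")) lognorm$values else lognorm
  if (ncol(v) < 10) stopf("need at least 10 genes for the LOESS fit")
  mu <- colMeans(v)
  if (any(mu <= 0)) stopf("all genes must have positive mean expression")
  cv <- apply(v, 2, stats::sd) / mu
  lmu <- log(mu)
  if (diff(range(lmu)) < 1e-12) stopf("degenerate LOESS fit: all gene means equal")
  fit <- stats::loess(cv ~ lmu, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  excess <- cv - stats::predict(fit, lmu)
  names(excess) <- colnames(v)
  cand <- excess[excess > 0]
  if (!length(cand)) stopf("no HV genes: no gene has positive CV excess")
  cut <- stats::quantile(cand, level_prob[[level]], names = FALSE, type = 7)
  keep <- sort(cand[cand >= cut], decreasing = TRUE)
  gene_selection(names(keep), unname(keep), "HVG_LOESS", level)
}

#' Row-standardized symmetrized k-nearest-neighbor spatial weights
#'
#' Binary kNN adjacency on Euclidean coordinate distance, symmetrized by
#' union, then row-standardized. No self-neighbors.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k_w number of nearest neighbors.
#' @return a sparse n x n weight matrix (class `dgCMatrix`).
#' @export
spatial_weights <- function(coords, k_w = 10) {
  n <- nrow(coords)
  if (k_w < 1 || k_w >= n) stopf("k_w must be in [1, n-1]")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_w)]))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_w),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  a <- ((a + Matrix::t(a)) > 0) * 1
  w <- a / Matrix::rowSums(a)
  methods::as(w, "CsparseMatrix")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the total weight. Positive for spatially smooth
#' patterns; returns `NA` ("undefined") for constant input.
#'
#' @param values per-cell numeric vector.
#' @param W spatial weight matrix (e.g. from [spatial_weights()]).
#' @return a single numeric value, or `NA` for constant input.
#' @export
morans_i <- function(values, W) {
  n <- length(values)
  if (n < 3) stopf("need at least 3 cells")
  if (n != nrow(W) || n != ncol(W)) stopf("W must be %d x %d", n, n)
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) return(NA_real_)
  s0 <- sum(W)
  (n / s0) * as.numeric(z %*% (W %*% z)) / ss
}

#' Select SV genes by a permutation Moran's I test
#'
#' Per gene, a one-sided permutation p-value
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm)` under random relabeling
#' of cells. `LOW` keeps genes with `p < 0.05`. The tighter levels keep the
#' smallest-p half (`MED`) and quarter (`HIGH`) of the `LOW`-passing genes,
#' so stringency increases monotonically with the level. A single seeded
#' set of permutations is shared across genes. Constant genes get `p = 1`.
#'
#' @param values cells x genes normalized expression matrix (columns named),
#'   or a `normalized_matrix`.
#' @param coords n x 2 coordinate matrix.
#' @param level threshold level.
#' @param n_perm number of permutations (at least 99).
#' @param k_w neighbors for the spatial weight graph.
#' @param seed integer seed for the permutations.
#' @param W optional precomputed weight matrix (overrides `coords`/`k_w`).
#' @return a `gene_selection` (method `SVG_MORAN`), p-value ascending, or
#'   the full p-value vector when `return_pvalues = TRUE`.
#' @param return_pvalues return the named per-gene p-value vector instead
#'   of a thresholded selection.
#' @export
select_svg_moran <- function(values, coords = NULL, level = "LOW",
                             n_perm = 999, k_w = 10, seed = 1L, W = NULL,
                             return_pvalues = FALSE) {
  if (inherits(values, "normalized_matrix")) values <- values$values
  if (n_perm < 99) stopf("n_perm must be at least 99")
  level <- check_level(level)
  W <- W %||% spatial_weights(coords, k_w)
  n <- nrow(values)
  z <- sweep(values, 2, colMeans(values))
  ss <- colSums(z^2)
  s0 <- sum(W)
  const <- ss == 0
  i_obs <- rep(NA_real_, ncol(values))
  wz <- as.matrix(W %*% z[, !const, drop = FALSE])
  i_obs[!const] <- (n / s0) * colSums(z[, !const, drop = FALSE] * wz) / ss[!const]
  set.seed(derive_seed(seed, 11L))
  perms <- replicate(n_perm, sample.int(n))
  pvals <- rep(1, ncol(values))
  for (j in which(!const)) {
    zp <- matrix(z[, j][perms], nrow = n)
    i_perm <- (n / s0) * colSums(zp * as.matrix(W %*% zp)) / ss[j]
    pvals[j] <- (1 + sum(i_perm >= i_obs[j])) / (1 + n_perm)
  }
  names(pvals) <- colnames(values)
  if (return_pvalues) return(pvals)
  low <- pvals[pvals < 0.05]
  if (!length(low)) stopf("no SV genes: no gene passes p < 0.05")
  keep <- low
  if (level != "LOW") {
    prob <- c(MED = 0.50, HIGH = 0.25)[[level]]
    cut <- stats::quantile(low, prob, names = FALSE, type = 7)
    keep <- low[low <= cut]
  }
  ord <- order(keep, names(keep))
  gene_selection(names(keep)[ord], unname(keep)[ord], "SVG_MORAN", level)
}

#' Concatenate HV and SV gene selections
#'
#' Deduplicated union preserving first-seen order (HV genes first), so each
#' gene appears at most once.
#'
#' @param hv,sv `gene_selection` objects from the same dataset.
#' @return a `gene_selection` with method `CONCAT`.
#' @export
concatenate_selections <- function(hv, sv) {
  ids <- c(hv$gene_ids, sv$gene_ids)
  stat <- c(hv$statistic, sv$statistic)
  dup <- duplicated(ids)
  gene_selection(ids[!dup], stat[!dup], "CONCAT", NA_character_)
}

#' Random ground-control gene set
#'
#' Samples `size` genes uniformly without replacement from the pool of
#' genes that are neither HV nor SV — the "ground control" condition used
#' to show that the concatenation's advantage is not mere gene-set size.
#'
#' @param ds a [spatial_dataset] (or character vector of all gene ids).
#' @param hv,sv `gene_selection` objects defining the exclusion.
#' @param size number of genes to draw (usually the concatenation size).
#' @param seed integer seed.
#' @param allow_short if the pool is smaller than `size`, return the whole
#'   pool instead of erroring.
#' @return a `gene_selection` with method `RANDOM`.
#' @export
random_control <- function(ds, hv, sv, size, seed = 1L, allow_short = FALSE) {
  all_genes <- if (inherits(ds, "spatial_dataset")) ds$gene_ids else as.character(ds)
  pool <- setdiff(all_genes, union(hv$gene_ids, sv$gene_ids))
  if (length(pool) < size) {
    if (!allow_short)
      stopf("random control pool has only %d genes (< requested %d)",
            length(pool), size)
    size <- length(pool)
  }
  if (!size) stopf("random control pool is empty")
  set.seed(derive_seed(seed, 13L))
  pick <- if (length(pool) == size) pool else sample(pool, size)
  gene_selection(pick, rep(NA_real_, length(pick)), "RANDOM", NA_character_)
}
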