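# Small in-code fixtures shared across test files.

# A tiny deterministic dataset with labels.
tiny_dataset <- function(n = 12, g = 6, seed = 1, labels = TRUE) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, 5), n, g)
  counts[1, 1] <- counts[1, 1] + 1  # guard against all-identical corner cases
  spatial_dataset(counts,
                  cbind(runif(n), runif(n)),
                  sprintf("cell%02d", seq_len(n)),
                  sprintf("gene%02d", seq_len(g)),
                  truth_labels = if (labels)
                    rep(c("A", "B"), length.out = n))
}

# A small but structured simulation: two segregated + two dispersed types.
small_config <- function(seed = 1, n_cells = 400, n_genes = 60, ...) {
  complementarity_config(n_cells = n_cells, n_genes = n_genes, seed = seed, ...)
}

# Wrap a plain matrix as a normalized_matrix for selection functions.
as_norm <- function(values, kind = "PEARSON_RESIDUAL") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  hvsvbench:::new_normalized_matrix(values, kind, list())
}

# Two well-separated Gaussian blobs in embedding space.
blob_embedding <- function(n_per = 50, dims = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * dims), n_per),
             matrix(rnorm(n_per * dims), n_per))
  x[(n_per + 1):(2 * n_per), 1] <- x[(n_per + 1):(2 * n_per), 1] + sep
  list(coords = x, labels = rep(0:1, each = n_per))
}

# Row-standardized rook adjacency on an r x c grid (cells in row-major
# order), for closed-form Moran checks.
rook_weights <- function(r, c) {
  n <- r * c
  W <- matrix(0, n, n)
  id <- function(i, j) (i - 1) * c + j
  for (i in seq_len(r)) for (j in seq_len(c)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= r && jj >= 1 && jj <= c) W[id(i, j), id(ii, jj)] <- 1
    }
  }
  W / rowSums(W)
}
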