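#' PCA embedding of a selected gene set
#'
#' Mean-centers the selected gene columns and keeps the top principal
#' components (capped at `min(n_pcs, cells - 1, genes)`).
#'
#' @param norm a `normalized_matrix` (gene columns named) or plain matrix.
#' @param genes a `gene_selection` restricting the columns.
#' @param n_pcs number of components to keep.
#' @return an `embedding`: list with `coords` (cells x n_pcs),
#'   `explained_var` fractions (non-increasing) and `gene_set_id`.
#' @export
pca_embed <- function(norm, genes = NULL, n_pcs = 50) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.null(genes)) {
    missing <- setdiff(genes$gene_ids, colnames(v))
    if (length(missing))
      stopf("%d selected genes absent from the matrix (first: %s)",
            length(missing), missing[1])
    v <- v[, genes$gene_ids, drop = FALSE]
  }
  if (ncol(v) < 2) stopf("need at least 2 genes to embed")
  n_pcs <- min(n_pcs, nrow(v) - 1L, ncol(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = n_pcs)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stopf("rank-0 input: no variance to embed")
  structure(list(coords = unname(pc$x), n_pcs = n_pcs,
                 explained_var = ev[seq_len(n_pcs)] / sum(ev),
                 gene_set_id = if (!is.null(genes))
                   paste0(genes$method, "/", genes$level) else "all"),
            class = "embedding")
}

# k nearest neighbors by Euclidean distance, self excluded,
# ties broken by cell index.
knn_index <- function(x, k, dists = NULL) {
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (k >= n) stopf("k must be < number of cells")
  d <- as.matrix(dists %||% if (inherits(x, "dist")) x else stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Shared-nearest-neighbor graph
#'
#' Each cell is connected to others by the Jaccard overlap of their
#' k-nearest-neighbor lists: `w(i,j) = |kNN(i) ∩ kNN(j)| / |kNN(i) ∪ kNN(j)|`.
#' Zero-weight edges are dropped; the graph is undirected.
#'
#' @param emb an `embedding` (or a plain matrix of cell coordinates).
#' @param k number of nearest neighbors (15 is the benchmark default).
#' @param dists optional precomputed `dist` object over the cells.
#' @param prune_below additionally drop edges with Jaccard weight below
#'   this value (0 keeps every positive-weight edge; `1/k` is the
#'   conventional pruning used by single-cell toolkits, and sparsifies
#'   the graph considerably).
#' @return an [igraph::graph] with edge attribute `weight`.
#' @export
build_snn <- function(emb, k = 15, dists = NULL, prune_below = 0) {
  x <- if (inherits(emb, "embedding")) emb$coords else emb
  if (k <= 0) stopf("k must be positive")
  n <- nrow(x)
  if (n <= k) stopf("need more than k = %d cells", k)
  nn <- knn_index(x, k, dists = dists)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)        # |kNN(i) ∩ kNN(j)|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j & shared@x > 0
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])
  if (prune_below > 0) {
    ok <- w >= prune_below
    i <- i[ok]; j <- j[ok]; w <- w[ok]
  }
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

# Adjusted Rand Index from the pair-counting contingency form; used to
# pick the medoid partition in the Leiden grid search.
ari_index <- function(a, b) {
  tab <- table(a, b)
  ss <- function(x) sum(choose(x, 2))
  sij <- ss(tab); sa <- ss(rowSums(tab)); sb <- ss(colSums(tab))
  expected <- sa * sb / choose(sum(tab), 2)
  mx <- (sa + sb) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Leiden clustering with resolution grid search and seed-majority vote
#'
#' For each resolution in the grid, Leiden (modularity objective) is run
#' `n_seeds` times under seeds `0..n_seeds-1`. A resolution qualifies when
#' the modal cluster count over its runs equals `K_target`. Within a
#' qualifying resolution, runs with exactly `K_target` clusters are kept
#' and the returned partition is their ARI-medoid — the run maximizing
#' mean pairwise Adjusted Rand Index with the other kept runs (the
#' "majority set"). When several resolutions qualify, the one whose kept
#' runs are most self-consistent (highest mean pairwise ARI) wins, ties
#' going to the lowest resolution.
#'
#' The search exploits that the cluster count grows with the resolution
#' under the modularity objective: a single-seed bisection first brackets
#' the grid interval where the count crosses `K_target`, and the full
#' `n_seeds` protocol is run on the grid points in (and, if needed,
#' progressively around) that band. `coarse = FALSE` runs the full
#' protocol on every grid point instead.
#'
#' @param graph an sNN graph from [build_snn()].
#' @param K_target required number of clusters (the ground-truth count).
#' @param resolutions resolution grid.
#' @param n_seeds runs per resolution.
#' @param coarse use the bisection bracket (default) or evaluate the whole
#'   grid.
#' @return a `cluster_labels` object: integer labels `0..K-1` plus the
#'   chosen resolution and seed set.
#' @export
leiden_grid_search <- function(graph, K_target,
                               resolutions = seq(0.05, 3, by = 0.05),
                               n_seeds = 10, coarse = TRUE) {
  n <- igraph::vcount(graph)
  if (K_target < 2) stopf("K_target must be at least 2")
  if (K_target > n) stopf("K_target = %d exceeds the %d cells", K_target, n)
  if (!length(resolutions)) stopf("empty resolution grid")
  run_leiden <- function(res, s) {
    set.seed(s)
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity", resolution = res,
      n_iterations = 2))
  }
  grid <- sort(resolutions)
  ng <- length(grid)
  achieved <- integer(0)

  # Full protocol at one resolution. A resolution qualifies outright when
  # the modal cluster count over its seeds equals K_target; resolutions
  # where only a minority of runs hit K_target are kept as fallbacks (the
  # published protocol keeps any run matching the ground-truth count).
  # Either way the candidate partition is the ARI-medoid of the runs with
  # exactly K_target clusters — the "majority set".
  evaluate <- function(res) {
    runs <- lapply(seq_len(n_seeds) - 1L, function(s) run_leiden(res, s))
    ks <- vapply(runs, function(m) length(unique(m)), 0L)
    achieved <<- c(achieved, ks)
    kept <- runs[ks == K_target]
    if (!length(kept)) return(NULL)
    modal_k <- as.integer(names(which.max(table(ks))))
    if (length(kept) == 1) {
      medoid <- kept[[1]]; consistency <- 1
    } else {
      arim <- outer(seq_along(kept), seq_along(kept),
                    Vectorize(function(i, j)
                      if (i == j) NA_real_ else ari_index(kept[[i]], kept[[j]])))
      mean_ari <- rowMeans(arim, na.rm = TRUE)
      medoid <- kept[[which.max(mean_ari)]]
      consistency <- mean(mean_ari)
    }
    list(membership = medoid, resolution = res, consistency = consistency,
         modal = modal_k == K_target, n_hit = length(kept))
  }

  if (coarse && ng > 8) {
    count1 <- function(i) {
      k <- length(unique(run_leiden(grid[i], 0L)))
      achieved <<- c(achieved, k)
      k
    }
    lo <- 1L; hi <- ng
    k_lo <- count1(lo); k_hi <- count1(hi)
    if (K_target <= k_lo) { hi <- lo
    } else if (K_target > k_hi) { lo <- hi
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (count1(mid) < K_target) lo <- mid else hi <- mid
      }
    }
    band <- max(1L, lo - 1L):min(ng, hi + 1L)
    center_out <- band[order(abs(band - (lo + hi) / 2))]
    order_idx <- c(center_out, setdiff(order(abs(seq_len(ng) - (lo + hi) / 2)), band))
  } else {
    order_idx <- seq_len(ng)
    band <- seq_len(ng)
  }

  best <- NULL; fallback <- NULL
  evaluated <- 0L
  better <- function(a, b) {     # is a better than b?
    is.null(b) || a$consistency > b$consistency + 1e-12 ||
      (abs(a$consistency - b$consistency) <= 1e-12 &&
       a$resolution < b$resolution)
  }
  for (i in order_idx) {
    r <- evaluate(grid[i])
    evaluated <- evaluated + 1L
    if (!is.null(r)) {
      if (r$modal) { if (better(r, best)) best <- r }
      else if (is.null(fallback) || r$n_hit > fallback$n_hit ||
               (r$n_hit == fallback$n_hit && better(r, fallback))) fallback <- r
    }
    # a qualifying resolution whose runs all but agree will not be beaten;
    # otherwise stop at the band edge as soon as something usable exists,
    # since further-out resolutions only drift away from K_target
    if (!is.null(best) && best$consistency >= 0.98) break
    if ((!is.null(best) || !is.null(fallback)) && evaluated >= length(band)) break
  }
  best <- best %||% fallback
  if (is.null(best))
    stopf("no resolution yields %d clusters (achieved counts %d..%d)",
          K_target, min(achieved), max(achieved))
  labels <- as.integer(factor(best$membership)) - 1L
  cluster_labels(labels, method = "leiden", resolution = best$resolution,
                 seeds = seq_len(n_seeds) - 1L)
}

#' Cluster labels container
#'
#' @param labels integer per-cell labels `0..K-1`.
#' @param method clustering method tag.
#' @param resolution Leiden resolution, if applicable.
#' @param seeds seeds used.
#' @param matched whether labels have been matched to truth ids (see
#'   [match_clusters()]).
#' @param matched_labels truth-id labels after matching.
#' @return a `cluster_labels` object.
#' @export
cluster_labels <- function(labels, method = "unknown", resolution = NULL,
                           seeds = NULL, matched = FALSE, matched_labels = NULL) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (!all(sort(unique(labels)) == seq_len(k) - 1L))
    stopf("labels must be consecutive integers 0..K-1")
  structure(list(labels = labels, k = k, method = method,
                 resolution = resolution, seeds = seeds, matched = matched,
                 matched_labels = matched_labels),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %d cells, K = %d (%s%s)\n",
              length(x$labels), x$k, x$method,
              if (x$matched) ", matched" else ""))
  invisible(x)
}

#' kmeans clustering with three distance variants
#'
#' Euclidean: Lloyd iterations on the embedding, best of `n_init` seeded
#' starts by within-cluster sum of squares. Pearson / Spearman: each row is
#' z-scored (after rank transformation for Spearman) so that squared
#' Euclidean distance is proportional to the correlation distance, then
#' Lloyd as above.
#'
#' @param emb an `embedding` or plain matrix.
#' @param K number of clusters.
#' @param distance one of `euclidean`, `pearson`, `spearman`.
#' @param n_init number of random starts.
#' @param seed integer seed.
#' @return a `cluster_labels` object.
#' @export
kmeans_cluster <- function(emb, K, distance = c("euclidean", "pearson", "spearman"),
                           n_init = 10, seed = 1L) {
  distance <- match.arg(distance)
  x <- if (inherits(emb, "embedding")) emb$coords else emb
  n <- nrow(x)
  if (K < 2 || K > n) stopf("K must be in [2, %d]", n)
  if (distance %in% c("pearson", "spearman")) {
    if (distance == "spearman") x <- t(apply(x, 1, rank))
    mu <- rowMeans(x); s <- apply(x, 1, stats::sd)
    if (any(s == 0)) stopf("constant rows cannot be correlation-normalized")
    x <- (x - mu) / s
  }
  set.seed(derive_seed(seed, 17L))
  km <- stats::kmeans(x, centers = K, nstart = n_init, iter.max = 100,
                      algorithm = "Lloyd")
  cluster_labels(km$cluster - 1L, method = paste0("kmeans-", distance),
                 seeds = seed)
}
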