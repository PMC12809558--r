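#' Adjusted Mutual Information
#'
#' Mutual information between two labelings, adjusted for chance by the
#' expected MI under the permutation (hypergeometric) model and normalized
#' by the arithmetic mean of the two label entropies:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`.
#' Identical labelings (up to renaming) score exactly 1; independent
#' labelings score near 0. Two single-class labelings are defined as 1.
#'
#' @param a,b label vectors of equal length.
#' @return a single numeric value (can be slightly negative).
#' @export
ami <- function(a, b) {
  if (length(a) != length(b))
    stopf("label vectors differ in length (%d vs %d)", length(a), length(b))
  if (length(a) < 2) stopf("need at least 2 observations")
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  # identical partition (bijective relabeling) -> exactly 1
  if (nrow(tab) == ncol(tab) &&
      sum(tab > 0) == nrow(tab) &&
      all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    return(1)
  h <- function(m) { p <- m[m > 0] / n; -sum(p * log(p)) }
  ha <- h(ai); hb <- h(bj)
  nz <- tab > 0
  mi <- sum((tab[nz] / n) * log(n * tab[nz] / (ai[row(tab)[nz]] * bj[col(tab)[nz]])))
  emi <- expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-14) return(0)
  (mi - emi) / denom
}

# Expected mutual information under the hypergeometric model with fixed
# marginals; log-factorial form for numerical stability.
expected_mi <- function(ai, bj, n) {
  lf <- lfactorial(0:n)
  emi <- 0
  for (x in ai) {
    for (y in bj) {
      nij <- max(1, x + y - n):min(x, y)
      nij <- nij[nij >= 1]
      if (!length(nij)) next
      lp <- lf[x + 1] + lf[y + 1] + lf[n - x + 1] + lf[n - y + 1] -
            lf[n + 1] - lf[nij + 1] - lf[x - nij + 1] - lf[y - nij + 1] -
            lf[n - x - y + nij + 1]
      emi <- emi + sum((nij / n) * log(n * nij / (x * y)) * exp(lp))
    }
  }
  emi
}

# Hungarian algorithm (shortest augmenting path / Jonker-Volgenant form):
# minimal-cost perfect matching on a square cost matrix. Returns, for each
# row, the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Match predicted clusters to truth classes by expression centroids
#'
#' Computes the mean expression profile of each predicted cluster and each
#' truth class (over the clustering gene set), their pairwise Pearson
#' correlations, and the one-to-one assignment maximizing total
#' correlation (optimal bipartite assignment). Surplus clusters on either
#' side stay unmatched; unmatched predicted clusters receive distinct
#' sentinel ids matching no truth label.
#'
#' @param pred a `cluster_labels` object (or integer vector).
#' @param truth per-cell truth labels.
#' @param expr cells x genes normalized expression matrix restricted to
#'   the clustering gene set (a `normalized_matrix` or plain matrix).
#' @return a `label_matching`: list with `map` (named: predicted cluster
#'   id -> truth id or sentinel), `similarity` matrix, and
#'   `matched_labels` (per-cell truth-id labels for the prediction).
#' @export
match_clusters <- function(pred, truth, expr) {
  labels <- if (inherits(pred, "cluster_labels")) pred$labels else as.integer(pred)
  v <- if (inherits(expr, "normalized_matrix")) expr$values else expr
  if (nrow(v) != length(labels) || length(truth) != length(labels))
    stopf("expression rows, predicted labels and truth labels must align")
  pk <- sort(unique(labels)); tk <- sort(unique(as.character(truth)))
  prof_p <- t(vapply(pk, function(k) colMeans(v[labels == k, , drop = FALSE]),
                     numeric(ncol(v))))
  prof_t <- t(vapply(tk, function(k) colMeans(v[truth == k, , drop = FALSE]),
                     numeric(ncol(v))))
  sim <- suppressWarnings(stats::cor(t(prof_p), t(prof_t)))
  sim[!is.finite(sim)] <- 0
  dimnames(sim) <- list(as.character(pk), tk)
  m <- max(length(pk), length(tk))
  cost <- matrix(max(sim) + 1, m, m)   # dummy padding, constant cost
  cost[seq_along(pk), seq_along(tk)] <- max(sim) - sim
  assign <- solve_assignment(cost)
  map <- setNames(rep(NA_character_, length(pk)), as.character(pk))
  for (r in seq_along(pk)) {
    j <- assign[r]
    if (j <= length(tk)) map[r] <- tk[j]
  }
  unmatched <- which(is.na(map))
  if (length(unmatched))
    map[unmatched] <- paste0(".unmatched", seq_along(unmatched))
  matched <- unname(map[as.character(labels)])
  structure(list(map = map, similarity = sim, matched_labels = matched),
            class = "label_matching")
}

#' Weighted F1 after cluster matching
#'
#' Predicted clusters are relabeled through a [match_clusters()] matching
#' (unmatched clusters become classes matching no truth label); per truth
#' class, the one-vs-rest F1 is computed, and the result is the average of
#' class F1 scores weighted by truth class size.
#'
#' @param pred a `cluster_labels` object or integer vector.
#' @param truth per-cell truth labels.
#' @param matching a `label_matching` from [match_clusters()].
#' @return weighted F1 in \[0, 1\].
#' @export
weighted_f1 <- function(pred, truth, matching) {
  matched <- matching$matched_labels
  truth <- as.character(truth)
  n <- length(truth)
  if (all(matched == truth)) return(1)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(k) {
    tp <- sum(matched == k & truth == k)
    fp <- sum(matched == k & truth != k)
    fn <- sum(matched != k & truth == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  w <- vapply(classes, function(k) sum(truth == k), 0) / n
  sum(w * f1)
}

#' Pearson Gamma (Hubert's Gamma, Pearson form)
#'
#' Correlation over all unordered point pairs between the pairwise
#' distance and the between-cluster indicator (1 when the pair is split
#' across clusters), so compact well-separated clusterings score near +1.
#' Pairs are enumerated exhaustively up to `max_exact_n` points and
#' uniformly subsampled (seeded) above that.
#'
#' @param d pairwise distances: a `dist` object, or a points matrix from
#'   which Euclidean distances are taken.
#' @param labels a `cluster_labels` object or label vector.
#' @param max_exact_n exhaustive enumeration limit.
#' @param n_pairs number of sampled pairs beyond the limit.
#' @param seed seed for pair subsampling.
#' @return Pearson Gamma in \[-1, 1\].
#' @export
pearson_gamma <- function(d, labels, max_exact_n = 5000, n_pairs = 1e6,
                          seed = 1L) {
  labels <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  n <- length(labels)
  if (n < 3) stopf("need at least 3 points")
  if (length(unique(labels)) < 2) stopf("Pearson Gamma undefined for a single cluster")
  if (!inherits(d, "dist")) {
    if (is.matrix(d) && nrow(d) == ncol(d) && isSymmetric(unname(d))) d <- stats::as.dist(d)
    else if (n <= max_exact_n) d <- stats::dist(d)
  }
  if (inherits(d, "dist")) {
    stopifnot(attr(d, "Size") == n)
    dd <- as.vector(d)
    li <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
    lj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
    between <- as.numeric(labels[li] != labels[lj])
  } else {
    set.seed(derive_seed(seed, 19L))
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    dd <- sqrt(rowSums((d[i, , drop = FALSE] - d[j, , drop = FALSE])^2))
    between <- as.numeric(labels[i] != labels[j])
  }
  if (stats::sd(dd) == 0 || stats::sd(between) == 0)
    stopf("Pearson Gamma undefined: constant distances or memberships")
  stats::cor(dd, between)
}

#' Entropy-weighted spatial neighborhoods
#'
#' The local neighborhood of cell `i` is the square window of half-side
#' `d` (Chebyshev metric, self included), where `d` is the `dist_pct`
#' quantile of the pairwise Euclidean distance distribution — i.e. 1% of
#' cell pairs are closer than `d` under the default. Each cell gets the
#' Shannon entropy (natural log) `e_i` of the truth-label proportions in
#' its window, and normalized weights `e*_i = e_i / sum(e_i)`.
#'
#' @param coords n x 2 cell coordinates.
#' @param truth per-cell truth labels.
#' @param dist_pct quantile of pairwise distances defining `d`.
#' @param max_exact_n exhaustive pairwise-distance limit; above it the
#'   quantile uses a seeded subsample of 5e6 pairs.
#' @param seed seed for the subsample.
#' @return a `neighborhood_index`: list with `d`, `neighbors` (list of
#'   index vectors), `entropy` (`e_i`), and `weights` (`e*_i`, summing to
#'   1 unless all entropies are 0).
#' @export
neighborhoods <- function(coords, truth, dist_pct = 0.01,
                          max_exact_n = 5000, seed = 1L) {
  n <- nrow(coords)
  if (n < 3) stopf("need at least 3 cells")
  truth <- as.character(truth)
  stopifnot(length(truth) == n)
  if (n <= max_exact_n) {
    d <- stats::quantile(stats::dist(coords), dist_pct, names = FALSE, type = 7)
  } else {
    set.seed(derive_seed(seed, 23L))
    i <- sample.int(n, 5e6, replace = TRUE)
    j <- sample.int(n, 5e6, replace = TRUE)
    ok <- i != j
    dd <- sqrt(rowSums((coords[i[ok], ] - coords[j[ok], ])^2))
    d <- stats::quantile(dd, dist_pct, names = FALSE, type = 7)
  }
  ord <- order(coords[, 1])
  xs <- coords[ord, 1]
  tf <- as.integer(factor(truth))
  ntypes <- max(tf)
  neighbors <- vector("list", n)
  entropy <- numeric(n)
  for (ii in seq_len(n)) {
    lo <- findInterval(coords[ii, 1] - d, xs) + 1L
    hi <- findInterval(coords[ii, 1] + d, xs)
    cand <- ord[lo:hi]
    nb <- cand[abs(coords[cand, 2] - coords[ii, 2]) <= d]
    neighbors[[ii]] <- nb
    p <- tabulate(tf[nb], nbins = ntypes)
    p <- p[p > 0] / length(nb)
    entropy[ii] <- if (length(p) > 1) -sum(p * log(p)) else 0
  }
  tot <- sum(entropy)
  weights <- if (tot > 0) entropy / tot else rep(0, n)
  structure(list(d = d, neighbors = neighbors, entropy = entropy,
                 weights = weights),
            class = "neighborhood_index")
}

check_matched <- function(pred, truth) {
  if (inherits(pred, "cluster_labels")) {
    if (is.null(pred$matched_labels))
      stopf("prediction must be matched to truth ids first (match_clusters)")
    pred <- pred$matched_labels
  }
  pred <- as.character(pred)
  if (length(pred) != length(truth)) stopf("label vectors must align")
  pred
}

#' Spatial Concordance
#'
#' Entropy-weighted per-cell agreement:
#' `SC = sum_i 1[u_i == u*_i] * e*_i`, where `u` is the truth, `u*` the
#' matched prediction and `e*_i` the normalized neighborhood entropy
#' weights — so a correct call in a heterogeneous (border) neighborhood
#' counts more than one deep inside a homogeneous region. SC is 1 iff the
#' prediction agrees with the truth at every cell with positive local
#' entropy, and 0 when it agrees at none.
#'
#' @param pred matched prediction: a matched `cluster_labels` or a vector
#'   of truth-id labels.
#' @param truth per-cell truth labels (the labeling the neighborhoods were
#'   built on).
#' @param nbhd a `neighborhood_index` from [neighborhoods()].
#' @return SC in \[0, 1\].
#' @export
spatial_concordance <- function(pred, truth, nbhd) {
  truth <- as.character(truth)
  pred <- check_matched(pred, truth)
  if (sum(nbhd$entropy) == 0) {
    if (all(pred == truth)) return(1)
    stopf("zero spatial heterogeneity: all neighborhood entropies are 0")
  }
  if (all(pred == truth)) return(1)
  sum(nbhd$weights[pred == truth])
}

#' Mean spatial AMI
#'
#' For each cell with positive neighborhood entropy, the AMI between the
#' truth and prediction labels restricted to its spatial window (clipped
#' to \[0,1\]); the result is the `e*_i`-weighted average. Cells whose
#' neighborhood is single-class in the truth carry zero weight.
#'
#' @inheritParams spatial_concordance
#' @return mean spatial AMI in \[0, 1\].
#' @export
mean_spatial_ami <- function(pred, truth, nbhd) {
  truth <- as.character(truth)
  pred <- check_matched(pred, truth)
  if (sum(nbhd$entropy) == 0) {
    if (all(pred == truth)) return(1)
    stopf("zero spatial heterogeneity: all neighborhood entropies are 0")
  }
  if (all(pred == truth)) return(1)
  idx <- which(nbhd$entropy > 0)
  local_ami <- vapply(idx, function(i) {
    nb <- nbhd$neighbors[[i]]
    min(1, max(0, ami(truth[nb], pred[nb])))
  }, 0)
  sum(nbhd$weights[idx] * local_ami)
}
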