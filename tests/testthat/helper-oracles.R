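# Independent brute-force reference implementations used as oracles.
# These deliberately re-derive each quantity with direct enumeration and
# elementary code, sharing nothing with the package implementations.

# Moran's I by explicit double sum.
oracle_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  W <- as.matrix(W)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * z[i] * z[j]
    s0 <- s0 + W[i, j]
  }
  (n / s0) * num / sum(z^2)
}

# Square-window neighborhoods, entropies and weights by O(n^2) scan.
oracle_nbhd <- function(coords, truth, dist_pct = 0.01) {
  n <- nrow(coords)
  dd <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    dd <- c(dd, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  d <- unname(quantile(dd, dist_pct, type = 7))
  nbrs <- vector("list", n); ent <- numeric(n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n))
      if (abs(coords[j, 1] - coords[i, 1]) <= d &&
          abs(coords[j, 2] - coords[i, 2]) <= d) nb <- c(nb, j)
    nbrs[[i]] <- nb
    p <- as.numeric(table(truth[nb])) / length(nb)
    ent[i] <- -sum(ifelse(p > 0, p * log(p), 0))
  }
  w <- if (sum(ent) > 0) ent / sum(ent) else rep(0, n)
  list(d = d, neighbors = nbrs, entropy = ent, weights = w)
}

oracle_sc <- function(pred, truth, onb) {
  s <- 0
  for (i in seq_along(truth)) if (pred[i] == truth[i]) s <- s + onb$weights[i]
  s
}

oracle_msami <- function(pred, truth, onb) {
  s <- 0
  for (i in seq_along(truth)) {
    if (onb$entropy[i] <= 0) next
    nb <- onb$neighbors[[i]]
    a <- oracle_ami(truth[nb], pred[nb])
    s <- s + onb$weights[i] * min(1, max(0, a))
  }
  s
}

# Mutual information of two labelings, direct definition.
oracle_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) for (y in unique(b)) {
    nij <- sum(a == x & b == y)
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (sum(a == x) * sum(b == y)))
  }
  mi
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# AMI with the expected MI taken literally as the average MI over every
# permutation of one labeling (the permutation model, enumerated).
# Exponential in n; only for n <= 7.
oracle_ami_enum <- function(a, b) {
  stopifnot(length(a) <= 7)
  perms <- all_permutations(seq_along(b))
  emi <- mean(vapply(perms, function(p) oracle_mi(a, b[p]), 0))
  h <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log(p))
  }
  denom <- (h(a) + h(b)) / 2 - emi
  if (abs(denom) < 1e-14) return(if (oracle_mi(a, b) >= emi) 1 else 0)
  (oracle_mi(a, b) - emi) / denom
}

# AMI with the hypergeometric expected MI written via choose(); used where
# n is too large to enumerate permutations.
oracle_ami <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  if (length(ua) == 1 && length(ub) == 1) return(1)
  emi <- 0
  for (x in ua) for (y in ub) {
    ai <- sum(a == x); bj <- sum(b == y)
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      pr <- exp(lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai))
      emi <- emi + pr * (nij / n) * log(n * nij / (ai * bj))
    }
  }
  h <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log(p))
  }
  mi <- oracle_mi(a, b)
  # identical partitions: report exactly 1 like any sane normalization
  tab <- table(a, b)
  if (nrow(tab) == ncol(tab) && sum(tab > 0) == nrow(tab) &&
      all(rowSums(tab > 0) == 1)) return(1)
  denom <- (h(a) + h(b)) / 2 - emi
  if (abs(denom) < 1e-14) return(0)
  (mi - emi) / denom
}

# Pearson Gamma by explicit pair enumeration and the textbook correlation
# formula.
oracle_pgamma <- function(points, labels) {
  n <- nrow(points)
  d <- c(); m <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, sqrt(sum((points[i, ] - points[j, ])^2)))
    m <- c(m, as.numeric(labels[i] != labels[j]))
  }
  num <- sum((d - mean(d)) * (m - mean(m)))
  num / sqrt(sum((d - mean(d))^2) * sum((m - mean(m))^2))
}

# Minimal-cost assignment by brute force over all permutations.
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf; best_p <- NULL
  for (p in all_permutations(seq_len(n))) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) { best <- tot; best_p <- p }
  }
  list(assignment = best_p, cost = best)
}
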