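test_that("AMI is exactly 1 on identical partitions and ~0 on independent ones", {
  a <- rep(c("x", "y", "z"), times = c(5, 3, 4))
  expect_true(ami(a, a) == 1)
  renamed <- c(x = "q", y = "r", z = "s")[a]
  expect_true(ami(a, renamed) == 1)

  set.seed(1)
  amis <- replicate(20, {
    u <- sample(1:4, 1000, replace = TRUE)
    v <- sample(1:4, 1000, replace = TRUE)
    ami(u, v)
  })
  expect_true(all(abs(amis) < 0.05))
  expect_error(ami(1:3, 1:4), "length")
})

test_that("AMI matches full permutation enumeration at tiny n", {
  cases <- list(
    list(a = c(1, 1, 2, 2, 3), b = c(1, 2, 2, 1, 3)),
    list(a = c(1, 1, 1, 2, 2, 2), b = c(1, 1, 2, 2, 3, 3)),
    list(a = c(1, 2, 1, 2, 1, 2, 1), b = c(2, 2, 2, 1, 1, 1, 1)),
    list(a = c(1, 1, 2, 2), b = c(3, 3, 3, 4)))
  for (cs in cases)
    expect_equal(ami(cs$a, cs$b), oracle_ami_enum(cs$a, cs$b),
                 tolerance = 1e-12)
  # and against the closed-form hypergeometric oracle at larger n
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(ami(a, b), oracle_ami(a, b), tolerance = 1e-12)
  }
})

test_that("the assignment solver is optimal", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    cost <- matrix(runif(k * k), k, k)
    got <- hvsvbench:::solve_assignment(cost)
    want <- oracle_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(k), got)]), want$cost,
                 tolerance = 1e-12)
  }
})

test_that("centroid matching recovers renamings and flags surplus clusters", {
  set.seed(4)
  n <- 90
  truth <- rep(c("A", "B", "C"), each = 30)
  expr <- matrix(rnorm(n * 9, 1), n, 9)
  for (k in 1:3) expr[truth == c("A", "B", "C")[k], (3 * k - 2):(3 * k)] <-
    expr[truth == c("A", "B", "C")[k], (3 * k - 2):(3 * k)] + 5

  pred_shift <- c(A = 1L, B = 2L, C = 0L)[truth]   # cyclic renaming
  m <- match_clusters(pred_shift, truth, expr)
  expect_identical(unname(m$map[c("0", "1", "2")]), c("C", "A", "B"))
  expect_identical(m$matched_labels, unname(truth))

  # brute force over all 6 bijections confirms the assignment is optimal
  best <- -Inf
  for (p in all_permutations(1:3)) {
    tot <- sum(m$similarity[cbind(1:3, p)])
    best <- max(best, tot)
  }
  chosen <- sum(m$similarity[cbind(1:3, match(m$map, c("A", "B", "C")))])
  expect_equal(chosen, best, tolerance = 1e-12)

  pred5 <- as.integer(factor(paste(truth, rep(1:2, length.out = n)))) - 1L
  m5 <- match_clusters(pred5, truth, expr)
  expect_identical(sum(startsWith(m5$map, ".unmatched")),
                   length(unique(pred5)) - 3L)
})

test_that("weighted F1 matches hand computations", {
  truth <- rep(c("A", "B"), each = 50)
  match_id <- structure(list(map = c(`0` = "A", `1` = "B"),
                             matched_labels = truth),
                        class = "label_matching")
  expect_true(weighted_f1(NULL, truth, match_id) == 1)

  all_a <- structure(list(map = c(`0` = "A"),
                          matched_labels = rep("A", 100)),
                     class = "label_matching")
  expect_equal(weighted_f1(NULL, truth, all_a), 1 / 3, tolerance = 1e-12)

  nm <- truth
  nm[1:10] <- ".unmatched1"
  some_nm <- structure(list(matched_labels = nm), class = "label_matching")
  expect_lt(weighted_f1(NULL, truth, some_nm), 1)
})

test_that("Pearson Gamma behaves on separated, random and relabeled input", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labs <- c(1, 1, 2, 2)
  expect_gt(pearson_gamma(pts, labs), 0.999)
  expect_equal(pearson_gamma(pts, labs), oracle_pgamma(pts, labs),
               tolerance = 1e-12)
  expect_equal(pearson_gamma(pts, labs), pearson_gamma(pts, 3 - labs),
               tolerance = 1e-15)

  set.seed(5)
  gs <- replicate(20, {
    cloud <- matrix(rnorm(500 * 2), 500, 2)
    pearson_gamma(cloud, sample(1:3, 500, replace = TRUE))
  })
  expect_true(all(abs(gs) < 0.1))
  expect_error(pearson_gamma(pts, rep(1, 4)), "single cluster")
})

test_that("neighborhood entropies follow the closed forms", {
  # four co-located cells with labels {A,A,B,B}: entropy ln 2 everywhere
  coords <- matrix(c(0, 0, 0.001, 0, 0, 0.001, 0.001, 0.001), 4, 2,
                   byrow = TRUE)
  far <- matrix(c(10, 10, 20, 20, 30, 30, 40, 40), 4, 2, byrow = TRUE)
  all_coords <- rbind(coords, far)
  truth <- c("A", "A", "B", "B", "A", "A", "B", "B")
  nb <- neighborhoods(all_coords, truth, dist_pct = 0.2)
  expect_equal(nb$entropy[1:4], rep(log(2), 4), tolerance = 1e-12)
  expect_equal(sum(nb$weights), 1, tolerance = 1e-12)

  # single-class truth: all entropies zero
  nb0 <- neighborhoods(all_coords, rep("A", 8), dist_pct = 0.2)
  expect_true(all(nb0$entropy == 0))
})

test_that("SC and MSAMI are 1 on perfect predictions and 0/low on wrecked ones", {
  gen <- generate_dataset(small_config(seed = 11))
  ds <- gen$dataset
  nb <- neighborhoods(ds$coords, ds$truth_labels)
  truth <- ds$truth_labels
  expect_true(spatial_concordance(truth, truth, nb) == 1)
  expect_true(mean_spatial_ami(truth, truth, nb) == 1)

  wrong <- c(SegA = "SegB", SegB = "DispA", DispA = "DispB",
             DispB = "SegA")[truth]
  expect_true(spatial_concordance(wrong, truth, nb) == 0)

  set.seed(12)
  perm <- sample(truth)
  expect_lt(mean_spatial_ami(perm, truth, nb), 0.2)
})

test_that("SC and MSAMI match their brute-force oracles", {
  for (rep in 1:6) {
    set.seed(rep + 30)
    n <- sample(25:50, 1)
    coords <- cbind(runif(n), runif(n))
    truth <- sample(c("A", "B", "C"), n, replace = TRUE)
    pred <- truth
    flip <- sample(n, 6)
    pred[flip] <- sample(c("A", "B", "C"), 6, replace = TRUE)
    onb <- oracle_nbhd(coords, truth, 0.05)
    nb <- neighborhoods(coords, truth, 0.05)
    expect_equal(nb$d, onb$d, tolerance = 1e-12)
    expect_equal(nb$entropy, onb$entropy, tolerance = 1e-12)
    if (any(pred != truth)) {
      expect_equal(spatial_concordance(pred, truth, nb),
                   oracle_sc(pred, truth, onb), tolerance = 1e-12)
      expect_equal(mean_spatial_ami(pred, truth, nb),
                   oracle_msami(pred, truth, onb), tolerance = 1e-12)
    }
  }
})

test_that("SC decreases monotonically and is border-sensitive", {
  set.seed(13)
  n <- 200
  coords <- cbind(runif(n), runif(n))
  truth <- ifelse(coords[, 1] < 0.5, "L", "R")
  nb <- neighborhoods(coords, truth, 0.05)
  pred <- truth
  last <- spatial_concordance(pred, truth, nb)
  for (i in sample(n, 30)) {
    pred[i] <- setdiff(c("L", "R"), truth[i])
    now <- spatial_concordance(pred, truth, nb)
    expect_lte(now, last + 1e-12)
    last <- now
  }

  border_cell <- which.min(abs(coords[, 1] - 0.5))
  interior_cell <- which.max(abs(coords[, 1] - 0.5))
  flip1 <- truth; flip1[border_cell] <- setdiff(c("L", "R"), truth[border_cell])
  flip2 <- truth; flip2[interior_cell] <- setdiff(c("L", "R"), truth[interior_cell])
  expect_lt(spatial_concordance(flip1, truth, nb),
            spatial_concordance(flip2, truth, nb))
})

test_that("spatial metrics demand matched labels", {
  gen <- generate_dataset(small_config(seed = 14))
  ds <- gen$dataset
  nb <- neighborhoods(ds$coords, ds$truth_labels)
  raw <- cluster_labels(as.integer(factor(ds$truth_labels)) - 1L)
  expect_error(spatial_concordance(raw, ds$truth_labels, nb), "matched")
})
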