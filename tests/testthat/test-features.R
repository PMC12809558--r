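# Build a matrix whose per-gene sample variances are exactly `v` (n = 4
# rows, mean 0): columns c(-a, a, -a, a) have variance 4a^2/3.
matrix_with_variances <- function(v) {
  cols <- vapply(v, function(vi) {
    a <- sqrt(3 * vi / 4)
    c(-a, a, -a, a)
  }, numeric(4))
  colnames(cols) <- sprintf("g%03d", seq_along(v))
  cols
}

test_that("residual-variance HVG selection gates at 1 then thresholds", {
  sel <- select_hvg_residual_variance(as_norm(matrix_with_variances(
    c(0.5, 0.9, 1.2))), "LOW")
  expect_identical(sel$gene_ids, "g003")

  m <- matrix_with_variances(2:11)
  for (lv in c("LOW", "MED", "HIGH")) {
    sel <- select_hvg_residual_variance(as_norm(m), lv)
    cut <- quantile(2:11, c(LOW = .5, MED = .7, HIGH = .9)[[lv]], type = 7)
    expect_setequal(sel$gene_ids,
                    sprintf("g%03d", which(2:11 >= cut - 1e-9)))
  }
  # HIGH keeps only the top gene: 90th percentile of 2..11 is 10.1
  expect_identical(select_hvg_residual_variance(as_norm(m), "HIGH")$gene_ids,
                   "g010")

  equal <- matrix_with_variances(rep(2, 6))
  for (lv in c("LOW", "MED", "HIGH"))
    expect_identical(length(select_hvg_residual_variance(as_norm(equal), lv)), 6L)

  expect_error(select_hvg_residual_variance(
    as_norm(matrix_with_variances(c(0.2, 0.4, 0.9))), "LOW"), "no HV genes")
})

test_that("LOESS CV selection finds inflated genes and nests by level", {
  set.seed(42)
  n <- 400
  mu <- exp(seq(log(2), log(20), length.out = 55))
  base_cv <- 0.2 + 0.5 / sqrt(mu)           # smooth mean-CV relationship
  inflated <- c(8, 18, 28, 38, 48)
  vals <- vapply(seq_along(mu), function(j) {
    cv <- base_cv[j] + if (j %in% inflated) 0.4 else 0
    sigma <- sqrt(log(1 + cv^2))
    rlnorm(n, log(mu[j]) - sigma^2 / 2, sigma)
  }, numeric(n))
  colnames(vals) <- sprintf("g%03d", seq_along(mu))
  sel <- select_hvg_loess_cv(as_norm(vals, "LOGNORM"), "LOW")
  expect_true(all(sprintf("g%03d", inflated) %in% sel$gene_ids))

  low <- select_hvg_loess_cv(as_norm(vals, "LOGNORM"), "LOW")
  med <- select_hvg_loess_cv(as_norm(vals, "LOGNORM"), "MED")
  high <- select_hvg_loess_cv(as_norm(vals, "LOGNORM"), "HIGH")
  expect_true(all(high$gene_ids %in% med$gene_ids))
  expect_true(all(med$gene_ids %in% low$gene_ids))

  flat <- matrix(rep(c(1, 2, 3, 2), 12), 4, 12)
  expect_error(select_hvg_loess_cv(as_norm(flat, "LOGNORM")), "degenerate|no HV")
})

test_that("spatial weights are a row-standardized symmetrized kNN graph", {
  set.seed(5)
  coords <- cbind(runif(40), runif(40))
  W <- spatial_weights(coords, k_w = 4)
  expect_true(all(Matrix::diag(W) == 0))
  expect_equal(unname(Matrix::rowSums(W)), rep(1, 40), tolerance = 1e-12)
  # union symmetrization: sparsity pattern is symmetric
  expect_true(all(((W != 0) - Matrix::t(W != 0)) == 0))
})

test_that("Moran's I is exactly -1 on the checkerboard and high on gradients", {
  W <- rook_weights(4, 4)
  vals <- rep(c(1, -1, 1, -1, -1, 1, -1, 1), 2)   # 4x4 checkerboard
  expect_equal(morans_i(vals, W), -1, tolerance = 1e-12)
  expect_true(is.na(morans_i(rep(2, 16), W)))

  # line graph: adjacent-neighbor weights, smooth gradient
  n <- 100
  Wl <- matrix(0, n, n)
  for (i in 1:(n - 1)) { Wl[i, i + 1] <- 1; Wl[i + 1, i] <- 1 }
  Wl <- Wl / rowSums(Wl)
  expect_gt(morans_i(seq_len(n), Wl), 0.9)
})

test_that("Moran's I agrees with the brute-force double sum", {
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(10:60, 1)
    coords <- cbind(runif(n), runif(n))
    W <- spatial_weights(coords, k_w = min(5, n - 2))
    v <- rnorm(n)
    expect_equal(morans_i(v, W), oracle_moran(v, W), tolerance = 1e-12)
  }
})

test_that("the Moran permutation test flags gradients and is seeded", {
  set.seed(10)
  n <- 400
  coords <- cbind(runif(n), runif(n))
  vals <- cbind(grad = coords[, 1] * 2 + rnorm(n, 0, 0.3),
                noise1 = rnorm(n), noise2 = rnorm(n))
  p1 <- select_svg_moran(vals, coords, n_perm = 199, seed = 3,
                         return_pvalues = TRUE)
  p2 <- select_svg_moran(vals, coords, n_perm = 199, seed = 3,
                         return_pvalues = TRUE)
  expect_identical(p1, p2)
  expect_identical(unname(p1["grad"]), 1 / 200)   # beats every permutation

  sel <- select_svg_moran(vals, coords, n_perm = 199, seed = 3)
  expect_identical(sel$gene_ids[1], "grad")
  # constant gene is undefined -> p = 1
  vals2 <- cbind(vals, const = rep(1, n))
  p3 <- select_svg_moran(vals2, coords, n_perm = 99, seed = 1,
                         return_pvalues = TRUE)
  expect_identical(unname(p3["const"]), 1)
})

test_that("SVG levels tighten monotonically", {
  gen <- generate_dataset(small_config(seed = 6))
  ds <- filter_rare_types(filter_outliers(gen$dataset))
  resid <- pearson_residuals(ds)
  sels <- lapply(c("LOW", "MED", "HIGH"), function(lv)
    select_svg_moran(resid, ds$coords, lv, n_perm = 99, k_w = 10, seed = 2))
  expect_true(all(sels[[3]]$gene_ids %in% sels[[2]]$gene_ids))
  expect_true(all(sels[[2]]$gene_ids %in% sels[[1]]$gene_ids))
  hvs <- lapply(c("LOW", "MED", "HIGH"), function(lv)
    select_hvg_residual_variance(resid, lv))
  expect_true(all(hvs[[3]]$gene_ids %in% hvs[[2]]$gene_ids))
  expect_true(all(hvs[[2]]$gene_ids %in% hvs[[1]]$gene_ids))
})

test_that("concatenation is a first-seen-order deduplicated union", {
  hv <- gene_selection(c("a", "b"), c(2, 1), "HVG_RESID", "LOW")
  sv <- gene_selection(c("b", "c"), c(.01, .02), "SVG_MORAN", "LOW")
  cc <- concatenate_selections(hv, sv)
  expect_identical(cc$gene_ids, c("a", "b", "c"))
  expect_identical(length(concatenate_selections(
    hv, gene_selection(c("x", "y"), c(1, 1), "SVG_MORAN", "LOW"))), 4L)
  expect_identical(concatenate_selections(
    hv, gene_selection("b", 1, "SVG_MORAN", "LOW"))$gene_ids, hv$gene_ids)
})

test_that("random controls avoid the HV and SV pools", {
  genes <- sprintf("g%03d", 1:200)
  hv <- gene_selection(genes[1:30], rep(2, 30), "HVG_RESID", "LOW")
  sv <- gene_selection(genes[21:60], rep(.01, 40), "SVG_MORAN", "LOW")
  rc <- random_control(genes, hv, sv, 50, seed = 1)
  expect_identical(length(rc), 50L)
  expect_length(intersect(rc$gene_ids, union(hv$gene_ids, sv$gene_ids)), 0)

  draws <- vapply(1:10, function(s)
    paste(sort(random_control(genes, hv, sv, 50, seed = s)$gene_ids),
          collapse = ","), "")
  expect_gt(length(unique(draws)), 1)

  pool_n <- 200L - 60L
  whole <- random_control(genes, hv, sv, pool_n, seed = 9)
  expect_setequal(whole$gene_ids, setdiff(genes, genes[1:60]))
  expect_error(random_control(genes, hv, sv, pool_n + 1, seed = 1), "pool")
  expect_identical(length(random_control(genes, hv, sv, pool_n + 1, seed = 1,
                                         allow_short = TRUE)), pool_n)
})
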