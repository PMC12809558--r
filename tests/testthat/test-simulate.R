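one_type <- function(frac_a = 0.5, mode_a = "dispersed", ...) {
  data.frame(name = c("A", "B"),
             fraction = c(frac_a, 1 - frac_a),
             mode = c(mode_a, "dispersed"),
             home_domain = c(if (mode_a == "segregated") 1L else NA, NA))
}

test_that("layout places every cell in its nearest Voronoi seed's domain", {
  cfg <- simulation_config(1000, 10, 2, one_type(),
                           c(NOISE = 10), seed = 11)
  lay <- make_layout(cfg)
  expect_setequal(unique(lay$domain_labels), 1:2)
  # brute-force nearest-seed check
  for (i in sample(1000, 50)) {
    d <- sqrt(rowSums((lay$centers - matrix(lay$coords[i, ], 2, 2,
                                            byrow = TRUE))^2))
    expect_identical(lay$domain_labels[i], which.min(d))
  }
  cfg1 <- simulation_config(50, 10, 1, one_type(), c(NOISE = 10))
  expect_true(all(make_layout(cfg1)$domain_labels == 1))
})

test_that("type assignment hits requested abundances and segregation", {
  cfg <- simulation_config(10000, 10, 2, one_type(0.5),
                           c(NOISE = 10), seed = 2)
  lay <- make_layout(cfg)
  types <- assign_types(cfg, lay$domain_labels)
  expect_true(abs(mean(types == "A") - 0.5) < 0.03)  # binomial 3-sigma

  ts <- data.frame(name = c("A", "B", "C"),
                   fraction = c(0.3, 0.3, 0.4),
                   mode = c("segregated", "segregated", "dispersed"),
                   home_domain = c(1L, 2L, NA))
  cfg2 <- simulation_config(2000, 10, 2, ts, c(NOISE = 10), p_home = 0.9,
                            domain_min_share = 0.45, seed = 3)
  lay2 <- make_layout(cfg2)
  types2 <- assign_types(cfg2, lay2$domain_labels)
  home_frac <- mean(lay2$domain_labels[types2 == "A"] == 1)
  expect_gte(home_frac, 0.85)
  # dispersed cells stay uniform over domains (within 3 sigma of share)
  share1 <- mean(lay2$domain_labels == 1)
  disp_frac <- mean(lay2$domain_labels[types2 == "C"] == 1)
  expect_lt(abs(disp_frac - share1), 3 * sqrt(0.25 / sum(types2 == "C")) + 0.02)
})

test_that("the mean model follows its closed form", {
  ts <- data.frame(name = c("A", "B"), fraction = c(0.5, 0.5),
                   mode = c("segregated", "dispersed"),
                   home_domain = c(1L, NA))
  base_cfg <- function(eff, grad) {
    simulation_config(200, 30, 2, ts,
                      c(SEG_MARKER = 10, DOMAIN_GRADIENT = 10, NOISE = 10),
                      effect_size = list(seg = eff, disp = 0),
                      gradient_amp = grad, seed = 5)
  }
  cfg <- base_cfg(0, 0)
  lay <- make_layout(cfg)
  types <- assign_types(cfg, lay$domain_labels)
  m <- build_mean_model(cfg, types, lay$domain_labels, lay$coords)
  expect_true(all(apply(m$log_means, 2, function(col) diff(range(col))) < 1e-12))

  cfg1 <- base_cfg(1, 0)
  m1 <- build_mean_model(cfg1, types, lay$domain_labels, lay$coords)
  j <- which(m1$gene_class == "SEG_MARKER")[1]
  tgt <- m1$gene_target[j]
  ratio <- exp(mean(m1$log_means[types == tgt, j]) -
               mean(m1$log_means[types != tgt, j]))
  expect_equal(ratio, exp(1), tolerance = 1e-9)

  cfg2 <- base_cfg(0, 2)
  m2 <- build_mean_model(cfg2, types, lay$domain_labels, lay$coords)
  for (j in which(m2$gene_class == "DOMAIN_GRADIENT"))
    expect_equal(diff(range(m2$log_means[, j])), 2, tolerance = 1e-9)
})

test_that("count sampling matches Poisson and NB moments", {
  lm <- matrix(log(5), 100000, 1)
  x <- sample_counts(lm, Inf, depth_mu = 0, depth_sigma = 0, seed = 1)
  expect_true(mean(x) > 4.93 && mean(x) < 5.07)  # Poisson 3-sigma

  lm2 <- matrix(log(10), 100000, 1)
  x2 <- sample_counts(lm2, 2, depth_mu = 0, depth_sigma = 0, seed = 2)
  # var = mu + mu^2/theta = 60, so var/mu = 6
  expect_true(var(as.vector(x2)) / mean(x2) > 5.7 &&
              var(as.vector(x2)) / mean(x2) < 6.3)
  expect_error(sample_counts(lm, -1, seed = 1), "theta")
})

test_that("generation is a pure function of the config", {
  cfg <- small_config(seed = 9)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(as.matrix(g1$dataset$counts), as.matrix(g2$dataset$counts))
  expect_identical(g1$dataset$truth_labels, g2$dataset$truth_labels)
  expect_identical(g1$annotation, g2$annotation)
})

test_that("the default scenario ships four abundant types", {
  gen <- generate_dataset(complementarity_config(n_cells = 2000,
                                                 n_genes = 300, seed = 1))
  tab <- table(gen$dataset$truth_labels)
  expect_identical(length(tab), 4L)
  expect_true(all(tab / 2000 >= 0.05))
})

test_that("a sub-5% type survives generation but not the rare-type filter", {
  ts <- data.frame(name = c("A", "B", "C"),
                   fraction = c(0.57, 0.40, 0.03),
                   mode = "dispersed", home_domain = NA)
  cfg <- simulation_config(1000, 20, 2, ts, c(NOISE = 20), seed = 4)
  ds <- generate_dataset(cfg)$dataset
  expect_true("C" %in% ds$truth_labels)
  kept <- filter_rare_types(ds)
  expect_false("C" %in% kept$truth_labels)
})

test_that("independent seeds give independent type labelings", {
  amis <- vapply(1:3, function(i) {
    a <- generate_dataset(small_config(seed = i))$dataset$truth_labels
    b <- generate_dataset(small_config(seed = i + 50))$dataset$truth_labels
    abs(ami(a, b))
  }, 0)
  expect_true(all(amis < 0.05))
})

test_that("config validation rejects inconsistent specs", {
  bad <- data.frame(name = c("A", "B"), fraction = c(0.6, 0.6),
                    mode = "dispersed", home_domain = NA)
  expect_error(simulation_config(10, 5, 1, bad, c(NOISE = 5)), "sum to 1")
  expect_error(simulation_config(10, 5, 1, one_type(), c(NOISE = 99)),
               "n_genes")
  ts <- one_type(0.5, "segregated"); ts$home_domain <- c(7L, NA)
  expect_error(simulation_config(10, 5, 2, ts, c(NOISE = 5)), "home_domain")
})
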