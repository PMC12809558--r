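#' Simulation configuration for synthetic spatial transcriptomics data
#'
#' Describes a tissue as `n_domains` Voronoi regions on the unit square,
#' populated by cell types that are either spatially *segregated* (most of
#' their cells live in one home domain) or *dispersed* (placed independently
#' of the domains), and a gene panel partitioned into classes:
#'
#' * `SEG_MARKER` — markers of segregated types (spatially coherent because
#'   their target type is; effect size `effect_size$seg` on the log-mean).
#' * `DISP_MARKER` — markers of dispersed types (high cell-to-cell variance,
#'   no spatial autocorrelation; effect size `effect_size$disp`).
#' * `DOMAIN_GRADIENT` — genes following a smooth spatial gradient of
#'   amplitude `gradient_amp` (log scale), independent of cell type.
#' * `NOISE` — baseline-only genes.
#' * `OUTLIER` — genes shifted `outlier_shift` log-units below baseline, to
#'   exercise low-expression outlier filtering.
#'
#' Counts are negative binomial with gene-shared dispersion `nb_dispersion`
#' and cell-specific lognormal library-size factors.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_domains number of Voronoi spatial domains.
#' @param type_spec data.frame with columns `name`, `fraction`, `mode`
#'   (`"segregated"` or `"dispersed"`) and `home_domain` (domain index for
#'   segregated types, `NA` otherwise). Fractions must sum to 1.
#' @param gene_class_counts named integer vector over the five gene classes;
#'   must sum to `n_genes`.
#' @param effect_size list with log-scale marker mean shifts `seg` and `disp`.
#' @param gradient_amp log-scale amplitude of `DOMAIN_GRADIENT` genes.
#' @param nb_dispersion negative binomial dispersion (size) shared by genes;
#'   `Inf` selects the Poisson limit.
#' @param depth_mu,depth_sigma lognormal parameters of per-cell library-size
#'   factors.
#' @param p_home probability mass a segregated type concentrates in its
#'   home domain (kept below 1 so types leak across borders).
#' @param baseline_log_range range of per-gene baseline log-means, drawn
#'   uniformly.
#' @param sv_baseline_boost log-units added to the baselines of
#'   `SEG_MARKER` and `DOMAIN_GRADIENT` genes; spatial markers are modeled
#'   as well-expressed panel genes, which keeps their residual variance
#'   low while their spatial autocorrelation stays detectable.
#' @param outlier_shift log-unit shift applied to `OUTLIER` genes.
#' @param outlier_cell_frac fraction of cells given an `outlier_shift`-sized
#'   depth deficit, emulating low-quality cells.
#' @param domain_min_share minimum fraction of cells each Voronoi domain
#'   must contain (0 only requires non-emptiness); layouts violating it are
#'   resampled.
#' @param seed integer seed; generation is a pure function of the config.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cells, n_genes, n_domains,
                              type_spec, gene_class_counts,
                              effect_size = list(seg = 0.3, disp = 1.5),
                              gradient_amp = 0.45,
                              nb_dispersion = 100,
                              depth_mu = 0, depth_sigma = 0.25,
                              p_home = 0.9,
                              baseline_log_range = c(log(1), log(4)),
                              sv_baseline_boost = 0,
                              outlier_shift = -4,
                              outlier_cell_frac = 0,
                              domain_min_share = 0,
                              seed = 1L) {
  type_spec <- as.data.frame(type_spec, stringsAsFactors = FALSE)
  gene_classes <- c("SEG_MARKER", "DISP_MARKER", "DOMAIN_GRADIENT", "NOISE", "OUTLIER")
  if (!all(c("name", "fraction", "mode") %in% names(type_spec)))
    stopf("type_spec needs columns name, fraction, mode")
  if (is.null(type_spec$home_domain)) type_spec$home_domain <- NA_integer_
  if (abs(sum(type_spec$fraction) - 1) > 1e-9)
    stopf("type fractions must sum to 1 (got %.6f)", sum(type_spec$fraction))
  if (!all(type_spec$mode %in% c("segregated", "dispersed")))
    stopf("type modes must be 'segregated' or 'dispersed'")
  seg <- type_spec$mode == "segregated"
  if (any(seg & (is.na(type_spec$home_domain) |
                 type_spec$home_domain < 1 | type_spec$home_domain > n_domains)))
    stopf("every segregated type must name a home_domain in 1..%d", n_domains)
  gcc <- gene_class_counts[gene_classes]
  gcc[is.na(gcc)] <- 0L
  names(gcc) <- gene_classes
  if (sum(gcc) != n_genes)
    stopf("gene_class_counts sum to %d, expected n_genes = %d", sum(gcc), n_genes)
  if (!is.finite(nb_dispersion) && !identical(nb_dispersion, Inf))
    stopf("nb_dispersion must be positive (or Inf for Poisson)")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  stopifnot(n_cells >= 1, n_genes >= 1, n_domains >= 1,
            p_home > 0, p_home <= 1, outlier_cell_frac >= 0, outlier_cell_frac < 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_domains = as.integer(n_domains), type_spec = type_spec,
                 gene_class_counts = gcc, effect_size = effect_size,
                 gradient_amp = gradient_amp, nb_dispersion = nb_dispersion,
                 depth_mu = depth_mu, depth_sigma = depth_sigma,
                 p_home = p_home, baseline_log_range = baseline_log_range,
                 sv_baseline_boost = sv_baseline_boost,
                 outlier_shift = outlier_shift,
                 outlier_cell_frac = outlier_cell_frac,
                 domain_min_share = domain_min_share,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default complementarity scenario
#'
#' Two segregated cell types distinguishable only through weak, spatially
#' coherent markers (detectable as SV genes) and two dispersed types
#' distinguishable only through strong, spatially unstructured markers
#' (detectable as HV genes) — so that neither gene set alone separates all
#' four types, while their concatenation does.
#'
#' @param n_cells,n_genes dataset dimensions (gene class counts scale with
#'   `n_genes`).
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
complementarity_config <- function(n_cells = 2000, n_genes = 300, seed = 1L, ...) {
  n_marker <- max(2L, round(0.10 * n_genes))
  n_seg <- max(2L, round(0.20 * n_genes))
  n_out <- max(1L, round(0.03 * n_genes))
  gcc <- c(SEG_MARKER = n_seg, DISP_MARKER = n_marker,
           DOMAIN_GRADIENT = n_marker, OUTLIER = n_out,
           NOISE = n_genes - n_seg - 2L * n_marker - n_out)
  types <- data.frame(name = c("SegA", "SegB", "DispA", "DispB"),
                      fraction = c(0.425, 0.425, 0.075, 0.075),
                      mode = c("segregated", "segregated", "dispersed", "dispersed"),
                      home_domain = c(1L, 2L, NA, NA))
  simulation_config(n_cells = n_cells, n_genes = n_genes, n_domains = 2,
                    type_spec = types, gene_class_counts = gcc,
                    effect_size = list(seg = 0.16, disp = 1.5),
                    gradient_amp = 0.30, p_home = 0.96,
                    nb_dispersion = 300, sv_baseline_boost = 1.0,
                    domain_min_share = 0.42,
                    outlier_cell_frac = 0.005, seed = seed, ...)
}

#' Place cells and spatial domains
#'
#' Cells are uniform on the unit square; domains are the Voronoi cells of
#' `n_domains` uniformly drawn seed points. Seed points are resampled (up
#' to 100 times) until every domain is non-empty.
#'
#' @param cfg a `simulation_config`.
#' @return list with `coords` (n x 2) and integer `domain_labels` in
#'   `1..n_domains`.
#' @export
make_layout <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  coords <- cbind(x = runif(cfg$n_cells), y = runif(cfg$n_cells))
  for (attempt in 1:100) {
    centers <- cbind(runif(cfg$n_domains), runif(cfg$n_domains))
    d2 <- outer(coords[, 1], centers[, 1], "-")^2 +
          outer(coords[, 2], centers[, 2], "-")^2
    dom <- max.col(-d2, ties.method = "first")
    shares <- tabulate(dom, cfg$n_domains) / cfg$n_cells
    if (all(shares > 0) && all(shares >= (cfg$domain_min_share %||% 0)))
      return(list(coords = coords, domain_labels = dom, centers = centers))
  }
  stopf("could not draw %d non-empty Voronoi domains (min share %.2f) for %d cells",
        cfg$n_domains, cfg$domain_min_share %||% 0, cfg$n_cells)
}

#' Assign cell types over a spatial layout
#'
#' Dispersed types are assigned independently of the domains. A segregated
#' type draws its cells with probability mass `p_home` concentrated on its
#' home domain (spread uniformly over that domain's still-unassigned cells)
#' and `1 - p_home` on the rest, so types leak across domain borders.
#'
#' @param cfg a `simulation_config`.
#' @param domain_labels integer domain per cell, from [make_layout()].
#' @param seed integer seed.
#' @return character vector of type names per cell.
#' @export
assign_types <- function(cfg, domain_labels, seed = cfg$seed) {
  set.seed(derive_seed(seed, 2L))
  n <- cfg$n_cells
  ts <- cfg$type_spec
  n_per <- floor(ts$fraction * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    extra <- order(ts$fraction * n - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  labels <- rep(NA_character_, n)
  avail <- seq_len(n)
  # Dispersed types first, drawn uniformly, so they stay independent of the
  # domains; segregated types then draw from a still spatially uniform pool.
  disp <- which(ts$mode == "dispersed")
  if (length(disp)) {
    pool <- sample(avail)
    offset <- 0L
    for (t in disp) {
      take <- pool[offset + seq_len(n_per[t])]
      labels[take] <- ts$name[t]
      offset <- offset + n_per[t]
    }
    avail <- setdiff(avail, pool[seq_len(offset)])
  }
  for (t in which(ts$mode == "segregated")) {
    home <- intersect(avail, which(domain_labels == ts$home_domain[t]))
    away <- setdiff(avail, home)
    if (length(home) < 1 || length(home) + length(away) < n_per[t])
      stopf("type '%s' abundance infeasible given domain sizes", ts$name[t])
    # binomial split of the type's cells between home and elsewhere,
    # capped by what is still unassigned on either side
    n_home <- stats::rbinom(1, n_per[t], cfg$p_home)
    n_home <- min(n_home, length(home))
    n_home <- max(n_home, n_per[t] - length(away))
    pick <- c(if (n_home > 0) sample(home, n_home),
              if (n_per[t] - n_home > 0) sample(away, n_per[t] - n_home))
    labels[pick] <- ts$name[t]
    avail <- setdiff(avail, pick)
  }
  if (anyNA(labels)) stopf("internal: %d cells left unassigned", sum(is.na(labels)))
  labels
}

#' Build the per-cell per-gene log-mean model
#'
#' Every gene gets a baseline log-mean drawn uniformly from
#' `baseline_log_range`. Marker genes add their class effect size on cells
#' of their target type; `DOMAIN_GRADIENT` genes add
#' `gradient_amp * f(coords)` where `f` is the cell coordinate projected on
#' a gene-specific random direction, min-max scaled to `[0, 1]`; `OUTLIER`
#' genes sit `outlier_shift` log-units below baseline.
#'
#' @param cfg a `simulation_config`.
#' @param type_labels per-cell type names.
#' @param domain_labels per-cell domains (unused by the default model, kept
#'   for alternative mean models).
#' @param coords n x 2 cell positions.
#' @param seed integer seed.
#' @return list with `log_means` (cells x genes), `gene_class`,
#'   `gene_target` (marker target type or `NA`), and `baseline` per gene.
#' @export
build_mean_model <- function(cfg, type_labels, domain_labels, coords,
                             seed = cfg$seed) {
  set.seed(derive_seed(seed, 3L))
  n <- cfg$n_cells; g <- cfg$n_genes
  gene_class <- rep(names(cfg$gene_class_counts), cfg$gene_class_counts)
  baseline <- runif(g, cfg$baseline_log_range[1], cfg$baseline_log_range[2])
  spatial <- gene_class %in% c("SEG_MARKER", "DOMAIN_GRADIENT")
  baseline[spatial] <- baseline[spatial] + (cfg$sv_baseline_boost %||% 0)
  seg_types <- cfg$type_spec$name[cfg$type_spec$mode == "segregated"]
  disp_types <- cfg$type_spec$name[cfg$type_spec$mode == "dispersed"]
  gene_target <- rep(NA_character_, g)
  lm <- matrix(rep(baseline, each = n), nrow = n)
  cycle <- function(pool, k) pool[(seq_len(k) - 1L) %% length(pool) + 1L]
  idx <- which(gene_class == "SEG_MARKER")
  if (length(idx)) {
    if (!length(seg_types)) stopf("SEG_MARKER genes require a segregated type")
    gene_target[idx] <- cycle(seg_types, length(idx))
    for (j in idx) lm[type_labels == gene_target[j], j] <-
        lm[type_labels == gene_target[j], j] + cfg$effect_size$seg
  }
  idx <- which(gene_class == "DISP_MARKER")
  if (length(idx)) {
    if (!length(disp_types)) stopf("DISP_MARKER genes require a dispersed type")
    gene_target[idx] <- cycle(disp_types, length(idx))
    for (j in idx) lm[type_labels == gene_target[j], j] <-
        lm[type_labels == gene_target[j], j] + cfg$effect_size$disp
  }
  idx <- which(gene_class == "DOMAIN_GRADIENT")
  for (j in idx) {
    ang <- runif(1, 0, 2 * pi)
    f <- coords[, 1] * cos(ang) + coords[, 2] * sin(ang)
    f <- (f - min(f)) / (max(f) - min(f))
    lm[, j] <- lm[, j] + cfg$gradient_amp * f
  }
  idx <- which(gene_class == "OUTLIER")
  if (length(idx)) lm[, idx] <- lm[, idx] + cfg$outlier_shift
  if (!all(is.finite(lm))) stopf("non-finite log-means in mean model")
  list(log_means = lm, gene_class = gene_class, gene_target = gene_target,
       baseline = baseline)
}

#' Sample UMI counts from the mean model
#'
#' Per-cell library factors are lognormal; counts are negative binomial
#' with mean `s_c * exp(log_mean)` and shared dispersion `theta`
#' (`theta = Inf` gives the Poisson limit).
#'
#' @param log_means cells x genes log-mean matrix.
#' @param theta NB dispersion (size); `Inf` for Poisson.
#' @param depth_mu,depth_sigma lognormal library-size parameters.
#' @param seed integer seed.
#' @param depth_factors optional per-cell factors overriding the lognormal
#'   draw (used for outlier cells).
#' @return integer cells x genes count matrix.
#' @export
sample_counts <- function(log_means, theta, depth_mu = 0, depth_sigma = 0.25,
                          seed = 1L, depth_factors = NULL) {
  if (theta <= 0) stopf("theta must be > 0")
  set.seed(derive_seed(seed, 4L))
  n <- nrow(log_means); g <- ncol(log_means)
  s <- depth_factors %||% rlnorm(n, depth_mu, depth_sigma)
  mu <- s * exp(log_means)
  x <- if (is.finite(theta)) rnbinom(n * g, mu = as.vector(mu), size = theta)
       else rpois(n * g, as.vector(mu))
  matrix(x, nrow = n, ncol = g)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Composes [make_layout()], [assign_types()], [build_mean_model()] and
#' [sample_counts()]; the dataset's `truth_labels` are the cell types.
#'
#' @param cfg a `simulation_config`.
#' @param bundle_dir optional directory: when given, the dataset is also
#'   written via [write_spatial_dataset()] together with `gene_classes.csv`
#'   and `domains.csv` annotation sidecars.
#' @return list with `dataset` (a [spatial_dataset]) and `annotation`
#'   (list of per-cell and per-gene ground-truth data.frames).
#' @export
generate_dataset <- function(cfg, bundle_dir = NULL) {
  layout <- make_layout(cfg)
  types <- assign_types(cfg, layout$domain_labels)
  model <- build_mean_model(cfg, types, layout$domain_labels, layout$coords)
  depth <- NULL
  if (cfg$outlier_cell_frac > 0) {
    set.seed(derive_seed(cfg$seed, 5L))
    depth <- rlnorm(cfg$n_cells, cfg$depth_mu, cfg$depth_sigma)
    n_out <- round(cfg$outlier_cell_frac * cfg$n_cells)
    if (n_out > 0) {
      out_cells <- sample.int(cfg$n_cells, n_out)
      depth[out_cells] <- depth[out_cells] * exp(cfg$outlier_shift)
    }
  }
  counts <- sample_counts(model$log_means, cfg$nb_dispersion,
                          cfg$depth_mu, cfg$depth_sigma,
                          seed = cfg$seed, depth_factors = depth)
  cell_ids <- sprintf("c%05d", seq_len(cfg$n_cells))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  ds <- spatial_dataset(counts, layout$coords, cell_ids, gene_ids,
                        truth_labels = types, platform_tag = "synthetic")
  ann <- list(
    cell = data.frame(cell_id = cell_ids, type = types,
                      domain = layout$domain_labels),
    gene = data.frame(gene_id = gene_ids, class = model$gene_class,
                      target = model$gene_target))
  if (!is.null(bundle_dir)) {
    write_spatial_dataset(ds, bundle_dir)
    utils::write.csv(ann$gene, file.path(bundle_dir, "gene_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(ann$cell[, c("cell_id", "domain")],
                     file.path(bundle_dir, "domains.csv"), row.names = FALSE)
  }
  list(dataset = ds, annotation = ann)
}
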