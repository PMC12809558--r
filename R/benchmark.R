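#' Benchmark configuration
#'
#' Collects every knob of the replicated experiment: the simulation
#' configs (or bundle paths) providing datasets, the gene-set conditions
#' to compare, selection and clustering parameters, and the metric list.
#'
#' @param datasets either a list of `simulation_config` objects or a
#'   character vector of bundle directories.
#' @param conditions subset of `HV`, `SV`, `CONCAT`, `RANDOM`.
#' @param hvg_method `resid` (residual variance) or `loess`.
#' @param hvg_level,svg_level selection threshold levels.
#' @param n_perm Moran permutations used for SV selection (199 keeps the
#'   p-value resolution at 0.005, ample for the 0.05 gate, at a fifth of
#'   the default test's cost).
#' @param k_w spatial-weight neighbors for Moran's I (a denser graph than
#'   the single-gene default narrows the permutation null and lets the
#'   test pick up markers whose variance is indistinguishable from noise).
#' @param n_pcs,k_snn,resolutions,n_seeds clustering parameters.
#' @param snn_prune sNN edge pruning threshold (the `1/k` convention).
#' @param metrics metric subset to compute.
#' @param dist_pct neighborhood quantile for the spatial metrics.
#' @param master_seed seed from which all per-dataset seeds derive.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(datasets,
                             conditions = c("HV", "SV", "CONCAT", "RANDOM"),
                             hvg_method = "resid",
                             hvg_level = "LOW", svg_level = "LOW",
                             n_perm = 199, k_w = 30,
                             n_pcs = 50, k_snn = 15, snn_prune = 1 / 15,
                             resolutions = seq(0.05, 3, by = 0.05),
                             n_seeds = 10,
                             metrics = c("AMI", "WF1", "PGAMMA", "SC", "MSAMI"),
                             dist_pct = 0.01,
                             master_seed = 1L) {
  stopifnot(length(datasets) >= 1)
  conditions <- match.arg(conditions, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(datasets = datasets, conditions = conditions,
                 hvg_method = hvg_method, hvg_level = hvg_level,
                 svg_level = svg_level, n_perm = n_perm, k_w = k_w,
                 n_pcs = n_pcs, k_snn = k_snn, snn_prune = snn_prune,
                 resolutions = resolutions,
                 n_seeds = n_seeds, metrics = metrics, dist_pct = dist_pct,
                 master_seed = as.integer(master_seed)),
            class = "benchmark_config")
}

# Load, simulate or adopt, then preprocess, one benchmark dataset.
prepare_dataset <- function(src, cfg, dataset_id) {
  ds <- if (inherits(src, "simulation_config")) generate_dataset(src)$dataset
        else if (inherits(src, "spatial_dataset")) src
        else read_spatial_dataset(src)
  if (is.null(ds$truth_labels))
    stopf("[%s] benchmark datasets need ground-truth labels", dataset_id)
  ds <- filter_outliers(ds)
  ds <- filter_rare_types(ds)
  ds
}

# Gene selections shared by every condition of one dataset.
select_gene_sets <- function(ds, cfg, dataset_id) {
  resid <- pearson_residuals(ds)
  hv <- if (identical(cfg$hvg_method, "loess"))
          select_hvg_loess_cv(lognormalize(ds), level = cfg$hvg_level)
        else select_hvg_residual_variance(resid, level = cfg$hvg_level)
  sv <- select_svg_moran(resid, ds$coords, level = cfg$svg_level,
                         n_perm = cfg$n_perm, k_w = cfg$k_w,
                         seed = derive_seed(cfg$master_seed, 29L))
  concat <- concatenate_selections(hv, sv)
  rand <- random_control(ds, hv, sv, size = length(concat),
                         seed = derive_seed(cfg$master_seed,
                                            31L + nchar(dataset_id) +
                                              sum(utf8ToInt(dataset_id))),
                         allow_short = TRUE)
  list(HV = hv, SV = sv, CONCAT = concat, RANDOM = rand, resid = resid)
}

#' Run one gene-set condition of the benchmark on one dataset
#'
#' Selects the condition's gene set, embeds it with PCA, builds the sNN
#' graph, runs the Leiden grid search at `K_target` = number of truth
#' classes, matches clusters to truth by expression centroids, and
#' computes the configured metrics. Deterministic given the config seeds.
#'
#' @param ds a preprocessed [spatial_dataset] with truth labels.
#' @param condition one of `HV`, `SV`, `CONCAT`, `RANDOM`.
#' @param cfg a `benchmark_config`.
#' @param dataset_id identifier used in the report rows.
#' @param cache optional precomputed `select_gene_sets()` output and/or
#'   `neighborhoods()` index, to share across conditions.
#' @return a metric report data.frame (one row per metric).
#' @export
run_condition <- function(ds, condition, cfg, dataset_id = "ds", cache = NULL) {
  sets <- cache$sets %||% select_gene_sets(ds, cfg, dataset_id)
  genes <- sets[[condition]]
  if (is.null(genes)) stopf("[%s/%s] unknown condition", dataset_id, condition)
  K <- length(unique(ds$truth_labels))
  emb <- pca_embed(sets$resid, genes, n_pcs = cfg$n_pcs)
  emb_dist <- stats::dist(emb$coords)
  graph <- build_snn(emb, k = cfg$k_snn, dists = emb_dist,
                     prune_below = cfg$snn_prune %||% 0)
  pred <- tryCatch(
    leiden_grid_search(graph, K, resolutions = cfg$resolutions,
                       n_seeds = cfg$n_seeds),
    error = function(e) stopf("[%s/%s] clustering failed: %s",
                              dataset_id, condition, conditionMessage(e)))
  expr_sel <- sets$resid$values[, genes$gene_ids, drop = FALSE]
  matching <- match_clusters(pred, ds$truth_labels, expr_sel)
  pred$matched <- TRUE
  pred$matched_labels <- matching$matched_labels
  nbhd <- cache$nbhd %||% neighborhoods(ds$coords, ds$truth_labels,
                                        dist_pct = cfg$dist_pct)
  vals <- c(
    AMI = if ("AMI" %in% cfg$metrics) ami(ds$truth_labels, pred$labels),
    WF1 = if ("WF1" %in% cfg$metrics)
            weighted_f1(pred, ds$truth_labels, matching),
    PGAMMA = if ("PGAMMA" %in% cfg$metrics)
               pearson_gamma(emb_dist, pred),
    SC = if ("SC" %in% cfg$metrics)
           spatial_concordance(pred, ds$truth_labels, nbhd),
    MSAMI = if ("MSAMI" %in% cfg$metrics)
              mean_spatial_ami(pred, ds$truth_labels, nbhd))
  vals["AMI"] <- if ("AMI" %in% cfg$metrics) max(0, min(1, vals[["AMI"]]))
  data.frame(dataset_id = dataset_id, condition = condition,
             method = "leiden", metric = names(vals),
             value = unname(vals), row.names = NULL)
}

#' Binomial thinning of UMI counts
#'
#' Retains each UMI independently with probability `rate`, emulating a
#' lower sequencing depth while preserving integrality.
#'
#' @param counts count matrix (sparse or dense) or a [spatial_dataset].
#' @param rate retention probability in (0, 1].
#' @param seed integer seed.
#' @return an object of the same kind with thinned counts.
#' @export
downsample_counts <- function(counts, rate, seed = 1L) {
  if (rate <= 0 || rate > 1) stopf("rate must be in (0, 1]")
  if (inherits(counts, "spatial_dataset")) {
    thinned <- downsample_counts(counts$counts, rate, seed)
    out <- counts
    out$counts <- methods::as(Matrix::drop0(thinned), "CsparseMatrix")
    return(out)
  }
  if (rate == 1) return(counts)
  set.seed(derive_seed(seed, 37L))
  if (inherits(counts, "sparseMatrix")) {
    counts@x <- as.double(stats::rbinom(length(counts@x), counts@x, rate))
    Matrix::drop0(counts)
  } else {
    matrix(stats::rbinom(length(counts), as.vector(counts), rate),
           nrow = nrow(counts), dimnames = dimnames(counts))
  }
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on per-dataset paired metric values; zero
#' differences are dropped (Wilcoxon's convention), the null distribution
#' is exact for up to 25 informative pairs without ties and the
#' tie-corrected normal approximation otherwise. All-zero differences
#' give `p = 1` with a flag.
#'
#' @param values_a,values_b paired per-dataset metric values.
#' @param label_a,label_b names for the two conditions.
#' @return a `comparison_result` data.frame row: statistic, two-sided p,
#'   median paired difference, number of informative pairs, and flags.
#' @export
wilcoxon_paired <- function(values_a, values_b, label_a = "A", label_b = "B") {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  nz <- d[d != 0]
  flag <- ""
  if (!length(nz)) {
    stat <- NA_real_; p <- 1.0; flag <- "all differences zero"
  } else {
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              paired = TRUE, exact = exact,
                                              correct = !exact))
    stat <- unname(ht$statistic); p <- ht$p.value
    if (length(nz) < 6) flag <- "fewer than 6 informative pairs"
  }
  data.frame(pair = paste0(label_a, " vs ", label_b),
             n_pairs = length(values_a), n_informative = length(nz),
             statistic = stat, p_value = p,
             median_diff = stats::median(d), flag = flag,
             stringsAsFactors = FALSE)
}

significance_stars <- function(p) {
  ifelse(p < 1e-3, "***", ifelse(p < 1e-2, "**",
         ifelse(p < 5e-2, "*", ifelse(p < 0.1, ".", ""))))
}

#' Run the full replicated benchmark
#'
#' For every dataset: preprocess, select the HV / SV / concatenated /
#' random-control gene sets once, run each configured condition, and
#' collect a pooled metric report. Conditions are then compared pairwise
#' per metric with paired Wilcoxon signed-rank tests, annotated with the
#' conventional significance bands (*** p < 1e-3, ** < 1e-2, * < 5e-2,
#' . < 0.1). Per-dataset failures are recorded and do not abort the run.
#'
#' @param cfg a `benchmark_config`.
#' @param out_dir optional output directory for `pooled.csv`,
#'   `comparisons.csv`, `summary.json` and `run.log`.
#' @return list with `report` (pooled metric report), `comparisons`,
#'   and `failures` (named character vector of error messages).
#' @export
run_benchmark <- function(cfg, out_dir = NULL) {
  ids <- names(cfg$datasets) %||%
    sprintf("ds%02d", seq_along(cfg$datasets))
  if (is.null(names(cfg$datasets)) && is.character(cfg$datasets))
    ids <- basename(cfg$datasets)
  rows <- list(); failures <- character(0)
  for (i in seq_along(cfg$datasets)) {
    id <- ids[i]
    res <- tryCatch({
      ds <- prepare_dataset(cfg$datasets[[i]], cfg, id)
      sets <- select_gene_sets(ds, cfg, id)
      nbhd <- neighborhoods(ds$coords, ds$truth_labels, dist_pct = cfg$dist_pct)
      do.call(rbind, lapply(cfg$conditions, function(cond)
        run_condition(ds, cond, cfg, dataset_id = id,
                      cache = list(sets = sets, nbhd = nbhd))))
    }, error = function(e) e)
    if (inherits(res, "error")) failures[id] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset_id = character(), condition = character(),
               method = character(), metric = character(), value = numeric())
  rownames(report) <- NULL
  comparisons <- NULL
  if (length(rows) >= 2 && length(cfg$conditions) >= 2) {
    pairs <- utils::combn(cfg$conditions, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(cfg$metrics, function(m) {
      do.call(rbind, lapply(pairs, function(pr) {
        a <- report[report$condition == pr[1] & report$metric == m, ]
        b <- report[report$condition == pr[2] & report$metric == m, ]
        common <- intersect(a$dataset_id, b$dataset_id)
        if (length(common) < 2) return(NULL)
        out <- wilcoxon_paired(a$value[match(common, a$dataset_id)],
                               b$value[match(common, b$dataset_id)],
                               pr[1], pr[2])
        cbind(metric = m, out, stars = significance_stars(out$p_value))
      }))
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(report)) write_metric_report(report, file.path(out_dir, "pooled.csv"))
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    summary <- list(
      n_datasets = length(cfg$datasets), n_failed = length(failures),
      master_seed = cfg$master_seed, conditions = cfg$conditions,
      medians = if (nrow(report))
        lapply(split(report$value,
                     paste(report$metric, report$condition, sep = ".")),
               stats::median))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(c(sprintf("master_seed: %d", cfg$master_seed),
                 sprintf("datasets: %s", paste(ids, collapse = ", ")),
                 sprintf("failures: %s",
                         if (length(failures))
                           paste(names(failures), failures, sep = ": ",
                                 collapse = "; ") else "none")),
               file.path(out_dir, "run.log"))
  }
  list(report = report, comparisons = comparisons, failures = failures)
}
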