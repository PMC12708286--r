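#' Validate a run configuration
#'
#' Fills defaults, rejects unknown keys and range-checks every
#' parameter. The configuration can come from a YAML file or a list.
#'
#' @param config path to a YAML file, or a named list (possibly empty).
#' @return a validated `mitodx_run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- list(
    lfc_min = 1.5, fdr = 0.05, sd_min = 0.5, min_module_size = 60,
    knn_k = 10, threshold = 0.5, seed = 1, min_features = 2,
    n_valid_cohorts = 3, skip_bench = FALSE, skip_combat = FALSE,
    sim = list(), out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  check_range <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < lo || v > hi) {
      stop(sprintf("configuration key '%s' out of range [%g, %g]", key, lo, hi))
    }
  }
  check_range("lfc_min", 0, Inf)
  check_range("fdr", 0, 1)
  check_range("sd_min", 0, Inf)
  check_range("min_module_size", 1, Inf)
  check_range("knn_k", 1, Inf)
  check_range("threshold", 0, 1)
  check_range("n_valid_cohorts", 1, Inf)
  class(cfg) <- "mitodx_run_config"
  cfg
}

log_event <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full discovery pipeline on simulated cohorts
#'
#' Orchestrates simulate -> preprocess (impute, log rule, quantile
#' normalization, merge, batch correction) -> differential expression ->
#' co-expression modules -> intersection funnel -> configuration
#' benchmark -> evaluation, and returns a machine-readable run summary.
#' Training cohorts are merged and batch-corrected; validation cohorts
#' are preprocessed per cohort and used only for evaluation.
#'
#' @param config a [validate_config()] result, list, or YAML path.
#' @param manifest benchmark manifest (default [default_manifest()]).
#' @return run summary list: `seed`, `n_degs`, `up`/`down` counts,
#'   `key_module` (+ `module_r`, `module_p`), `hub_genes`, `venn`,
#'   `top_model` (label, C-index, per-cohort AUCs, features), training
#'   confusion `rates`, plus the heavyweight stage objects in
#'   `artifacts`. If `out_dir` is set, stage TSVs and `summary.json`
#'   are written there.
#' @export
run_discovery <- function(config = list(), manifest = default_manifest()) {
  cfg <- if (inherits(config, "mitodx_run_config")) config else validate_config(config)
  seed <- cfg$seed

  log_event("simulate", "generating cohorts")
  sim_args <- cfg$sim
  sim_args$seed <- derive_seed(seed, "simulate")
  n_train <- sim_args$n_cohorts %||% 3
  sim_args$n_cohorts <- n_train + cfg$n_valid_cohorts
  sim <- simulate_cohorts(do.call(sim_config, sim_args))
  cohorts <- names(sim$matrices)
  train_cohorts <- cohorts[seq_len(n_train)]
  valid_cohorts <- setdiff(cohorts, train_cohorts)

  log_event("preprocess", "imputation, log rule, quantile normalization")
  prep <- lapply(sim$matrices, function(m) {
    if (anyNA(m)) m <- knn_impute(m, k = cfg$knn_k)
    m <- auto_log2(m)$matrix
    quantile_normalize(m)
  })
  merged <- merge_cohorts(prep[train_cohorts])
  pheno <- sim$pheno
  group_of <- setNames(pheno$group, pheno$sample_id)
  train_groups <- group_of[colnames(merged$matrix)]
  if (!cfg$skip_combat) {
    log_event("preprocess", "batch correction")
    merged$matrix <- combat_adjust(merged$matrix, merged$cohort_of, train_groups)
  }

  log_event("dge", "moderated-t differential expression")
  dge <- run_dge(merged$matrix, train_groups, lfc_min = cfg$lfc_min, fdr = cfg$fdr)
  degs <- union(dge$up, dge$down)

  log_event("coexpr", "module detection")
  trait <- as.numeric(train_groups == "Treat")
  coexpr <- run_coexpr(merged$matrix, trait, sd_min = cfg$sd_min,
                       min_module_size = cfg$min_module_size)
  key_row <- coexpr$module_trait[coexpr$module_trait$module == coexpr$key_module, ]

  log_event("intersect", "DEG / key-module / mitochondrial funnel")
  funnel <- intersect_hub(degs, coexpr$module_genes, sim$truth$mito_genes)
  summary <- list(
    seed = seed,
    n_degs = length(degs), n_up = length(dge$up), n_down = length(dge$down),
    key_module = coexpr$key_module, module_r = key_row$r, module_p = key_row$p,
    soft_power = coexpr$beta,
    hub_genes = funnel$hub, venn = as.list(funnel$venn)
  )
  artifacts <- list(sim = sim, merged = merged, dge = dge, coexpr = coexpr,
                    funnel = funnel)

  if (!cfg$skip_bench) {
    if (!length(funnel$hub)) {
      stop("empty hub set: no genes survive the intersection funnel; ",
           "cannot benchmark")
    }
    log_event("bench", sprintf("benchmark over hub set of %d genes",
                               length(funnel$hub)))
    train <- list(X = t(merged$matrix[funnel$hub, , drop = FALSE]),
                  y = as_binary_labels(train_groups))
    validations <- lapply(setNames(valid_cohorts, valid_cohorts), function(cname) {
      m <- prep[[cname]]
      list(X = t(m[funnel$hub, , drop = FALSE]),
           y = as_binary_labels(group_of[colnames(m)]))
    })
    bench <- run_benchmark(enumerate_configs(manifest), train, validations,
                           seed = derive_seed(seed, "bench"),
                           min_features = cfg$min_features)
    log_event("evaluate", "confusion matrix of the top model on training data")
    top_fit <- bench$top$fit
    train_scores <- predict_prob(top_fit, train$X)
    cm <- confusion_at_threshold(train_scores, train$y, threshold = cfg$threshold)
    summary$top_model <- list(
      label = bench$top$label, cindex = bench$top$cindex,
      auc = as.list(bench$top$auc), train_auc = bench$top$train_auc,
      n_selected = bench$top$n_selected,
      features = bench$top$selected_features
    )
    summary$train_confusion <- cm
    summary$train_rates <- as.list(confusion_rates(cm))
    artifacts$bench <- bench
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_tsv(merged$matrix, file.path(cfg$out_dir, "merged_corrected.tsv"))
    write.table(dge$table, file.path(cfg$out_dir, "dge.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = names(coexpr$partition),
                           module = unname(coexpr$partition)),
                file.path(cfg$out_dir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(artifacts$bench)) {
      write.table(artifacts$bench$table, file.path(cfg$out_dir, "benchmark.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary$artifacts <- artifacts
  invisible(summary)
}
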