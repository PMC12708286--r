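#' Default benchmark manifest
#'
#' The shipped composition of the 113 configurations: 15 selector
#' variants (Lasso; Enet with alpha 0.1...0.9; StepGLM both/backward/
#' forward; glmBoost; RF) crossed with 7 modelers (Ridge, SVM, LDA,
#' NaiveBayes, XGBoost, GBM, plsRglm) gives 105 two-stage pairs, plus 8
#' standalone models (the 7 modelers and Lasso). The manifest is an
#' editable list so restricted benchmarks can be enumerated the same way.
#'
#' @return list with `selectors` and `modelers` (lists of argument lists
#'   for [learner_spec()]) and `standalones`.
#' @export
default_manifest <- function() {
  list(
    selectors = c(
      list(list(algorithm = "Lasso")),
      lapply(seq(0.1, 0.9, by = 0.1),
             function(a) list(algorithm = "Enet", alpha = a)),
      lapply(c("both", "backward", "forward"),
             function(d) list(algorithm = "StepGLM", direction = d)),
      list(list(algorithm = "GlmBoost"), list(algorithm = "RF"))
    ),
    modelers = list(
      list(algorithm = "Ridge"), list(algorithm = "SVM"),
      list(algorithm = "LDA"), list(algorithm = "NaiveBayes"),
      list(algorithm = "XGBoost"), list(algorithm = "GBM"),
      list(algorithm = "PlsRglm")
    ),
    standalones = list(
      list(algorithm = "Ridge"), list(algorithm = "SVM"),
      list(algorithm = "LDA"), list(algorithm = "NaiveBayes"),
      list(algorithm = "XGBoost"), list(algorithm = "GBM"),
      list(algorithm = "PlsRglm"), list(algorithm = "Lasso")
    )
  )
}

#' Enumerate selector-by-modeler configurations from a manifest
#'
#' @param manifest a manifest as returned by [default_manifest()].
#' @return list of `mitodx_model_config` objects, each with `selector`
#'   (a spec or `NULL`), `modeler` and a unique `label` such as
#'   `"glmBoost+LDA"` or standalone `"Ridge"`.
#' @export
enumerate_configs <- function(manifest = default_manifest()) {
  selectors <- lapply(manifest$selectors, function(a) do.call(learner_spec, a))
  modelers <- lapply(manifest$modelers, function(a) do.call(learner_spec, a))
  standalones <- lapply(manifest$standalones, function(a) do.call(learner_spec, a))
  bad <- selectors[!vapply(selectors, `[[`, TRUE, "can_select")]
  if (length(bad)) {
    stop("manifest lists non-selecting algorithm(s) as selectors: ",
         paste(vapply(bad, `[[`, "", "label"), collapse = ", "))
  }
  configs <- list()
  for (s in selectors) {
    for (m in modelers) {
      configs[[length(configs) + 1L]] <- structure(
        list(selector = s, modeler = m,
             label = paste0(s$label, "+", m$label)),
        class = "mitodx_model_config")
    }
  }
  for (m in standalones) {
    configs[[length(configs) + 1L]] <- structure(
      list(selector = NULL, modeler = m, label = m$label),
      class = "mitodx_model_config")
  }
  labels <- vapply(configs, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate configuration labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  configs
}

#' Fit and evaluate one selector-modeler configuration
#'
#' The selector (if any) is fitted on the training cohort and its
#' surviving features become the modeler's inputs (the "subFeature"
#' contract); configurations whose selection drops below `min_features`
#' are skipped. The fitted modeler is scored on every validation cohort
#' by AUC; the mean validation AUC is reported as the C-index (they
#' coincide for a binary outcome).
#'
#' @param config a `mitodx_model_config`.
#' @param train list with `X` (samples x features) and `y` labels.
#' @param validations named list of such lists (one per cohort).
#' @param seed integer seed (per-stage seeds derive from it and the label).
#' @param min_features minimum surviving features to proceed (default 2).
#' @param selector_cache optional environment memoizing selector fits
#'   across configurations sharing a selector (selection does not depend
#'   on the downstream modeler; its seed derives from the selector label
#'   alone, so cached and uncached runs agree).
#' @return a `BenchmarkResult` list: `label`, `status`, `n_selected`,
#'   `selected_features`, `auc` (named per validation cohort),
#'   `train_auc`, `cindex` (mean validation AUC), `fit`.
#' @export
run_combo <- function(config, train, validations, seed = 1, min_features = 2,
                      selector_cache = NULL) {
  for (v in validations) {
    if (!all(colnames(train$X) %in% colnames(v$X))) {
      stop("validation cohorts lack training features")
    }
  }
  features <- colnames(train$X)
  if (!is.null(config$selector)) {
    sel_label <- config$selector$label
    sel_fit <- if (!is.null(selector_cache) && !is.null(selector_cache[[sel_label]])) {
      selector_cache[[sel_label]]
    } else {
      fit_learner(config$selector, train$X, train$y,
                  seed = derive_seed(seed, paste0(sel_label, "/selector")))
    }
    if (!is.null(selector_cache)) selector_cache[[sel_label]] <- sel_fit
    features <- extract_features(sel_fit)
    if (length(features) < min_features) {
      return(list(label = config$label, status = "skipped",
                  n_selected = length(features), selected_features = features,
                  auc = NULL, train_auc = NA_real_, cindex = NA_real_))
    }
  }
  fit <- fit_learner(config$modeler, train$X[, features, drop = FALSE], train$y,
                     seed = derive_seed(seed, paste0(config$label, "/modeler")))
  auc <- vapply(validations, function(v) {
    roc_auc(predict_prob(fit, v$X), v$y)
  }, 1)
  list(label = config$label, status = "ok",
       n_selected = length(features), selected_features = features,
       auc = auc, train_auc = roc_auc(predict_prob(fit, train$X), train$y),
       cindex = mean(auc), fit = fit)
}

#' Run and rank a full configuration benchmark
#'
#' Results are ranked by mean validation AUC (descending), ties broken by
#' fewer selected features then by label. The training-cohort AUC is
#' reported alongside but never enters the ranking mean.
#'
#' @param configs list from [enumerate_configs()].
#' @param train,validations as in [run_combo()].
#' @param seed master seed; per-configuration seeds are derived by a
#'   stable hash of the label.
#' @param min_features passed to [run_combo()].
#' @param scale_data centre and scale features using training-cohort
#'   means and standard deviations before fitting (default `FALSE`, the
#'   framework's convention); tree-based models are unaffected by it.
#' @param keep_fits retain fitted models (default only the top one).
#' @return list with `table` (ranked data.frame: `label`, `cindex`,
#'   `train_auc`, `n_selected`, `status`, one column per validation
#'   cohort), `auc_matrix` (configs x cohorts), `top` (the best
#'   `BenchmarkResult` including its fit).
#' @export
run_benchmark <- function(configs, train, validations, seed = 1,
                          min_features = 2, scale_data = FALSE,
                          keep_fits = FALSE) {
  if (!length(configs)) stop("no configurations to run")
  if (is.null(names(validations))) {
    names(validations) <- sprintf("cohort%d", seq_along(validations))
  }
  if (scale_data) {
    centers <- colMeans(train$X)
    scales <- apply(train$X, 2, sd)
    scales[scales == 0] <- 1
    rescale <- function(d) {
      d$X <- scale(d$X, center = centers[colnames(d$X)],
                   scale = scales[colnames(d$X)])
      d
    }
    train <- rescale(train)
    validations <- lapply(validations, rescale)
  }
  cache <- new.env(parent = emptyenv())
  results <- lapply(configs, function(cfg) {
    run_combo(cfg, train, validations, seed = seed,
              min_features = min_features, selector_cache = cache)
  })
  labels <- vapply(results, `[[`, "", "label")
  cindex <- vapply(results, `[[`, 1, "cindex")
  nsel <- vapply(results, `[[`, 1L, "n_selected")
  status <- vapply(results, `[[`, "", "status")
  auc_matrix <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$auc)) setNames(rep(NA_real_, length(validations)),
                                 names(validations)) else r$auc
  }))
  dimnames(auc_matrix) <- list(labels, names(validations))
  ord <- order(-ifelse(is.na(cindex), -Inf, cindex), nsel, labels)
  table <- data.frame(
    label = labels, cindex = cindex,
    train_auc = vapply(results, `[[`, 1, "train_auc"),
    n_selected = nsel, status = status,
    auc_matrix, check.names = FALSE, stringsAsFactors = FALSE
  )[ord, ]
  rownames(table) <- NULL
  top <- results[[ord[1]]]
  if (!keep_fits) {
    results <- lapply(results, function(r) { r$fit <- NULL; r })
  }
  list(table = table, auc_matrix = auc_matrix[ord, , drop = FALSE],
       top = top, results = results)
}
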