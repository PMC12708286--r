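# Algorithms able to act as feature selectors (non-trivial ExtractVar):
# penalized GLMs drop zero coefficients, stepwise returns entered terms,
# tree ensembles keep positive importance. SVM, LDA, XGBoost and
# NaiveBayes always use all features.
.selector_algorithms <- c("Lasso", "Enet", "StepGLM", "GlmBoost", "PlsRglm",
                          "RF", "GBM")
.all_algorithms <- c("Lasso", "Ridge", "Enet", "StepGLM", "SVM", "GlmBoost",
                     "LDA", "PlsRglm", "RF", "GBM", "XGBoost", "NaiveBayes")

#' Describe one base learner
#'
#' @param algorithm one of `Lasso`, `Ridge`, `Enet`, `StepGLM`, `SVM`,
#'   `GlmBoost`, `LDA`, `PlsRglm`, `RF`, `GBM`, `XGBoost`, `NaiveBayes`.
#' @param alpha elastic-net mixing for `Enet` (one of 0.1...0.9;
#'   `Lasso` is alpha = 1, `Ridge` alpha = 0 and both are fixed).
#' @param direction stepwise direction for `StepGLM`
#'   (`both`/`backward`/`forward`).
#' @return a `mitodx_learner_spec` with capability flags `can_select`,
#'   `can_model` and a display `label`.
#' @export
learner_spec <- function(algorithm, alpha = NULL, direction = NULL) {
  algorithm <- match.arg(algorithm, .all_algorithms)
  if (algorithm == "Enet") {
    if (is.null(alpha) || !alpha %in% seq(0.1, 0.9, by = 0.1)) {
      stop("Enet requires alpha in {0.1, ..., 0.9}")
    }
  } else if (algorithm == "Lasso") alpha <- 1
  else if (algorithm == "Ridge") alpha <- 0
  else alpha <- NULL
  if (algorithm == "StepGLM") {
    direction <- match.arg(direction %||% "both", c("both", "backward", "forward"))
  } else direction <- NULL
  label <- switch(algorithm,
    Enet = sprintf("Enet[α=%.1f]", alpha),
    StepGLM = sprintf("StepGLM[%s]", direction),
    GlmBoost = "glmBoost",
    PlsRglm = "plsRglm",
    algorithm
  )
  structure(list(algorithm = algorithm, alpha = alpha, direction = direction,
                 can_select = algorithm %in% .selector_algorithms,
                 can_model = TRUE, label = label),
            class = "mitodx_learner_spec")
}

#' Fit a base learner on a binary classification problem
#'
#' All learners share one contract: fit on a samples x features matrix
#' and 0/1 labels (1 = Treat), expose a probability prediction for the
#' positive class via [predict_prob()] and a selected-feature list via
#' [extract_features()]. Fits are deterministic given `seed`.
#'
#' Per-algorithm behaviour: penalized logistic models (`Lasso`, `Ridge`,
#' `Enet`) choose lambda at the 10-fold cross-validated deviance minimum;
#' `StepGLM` is AIC-guided stepwise logistic regression; `SVM` a radial
#' kernel with probability calibration; `GlmBoost` componentwise gradient
#' boosting of the logistic loss with the stopping iteration chosen by
#' 10-fold CV; `PlsRglm` logistic regression on PLS components with the
#' component count chosen by 10-fold CV misclassification; `RF` a
#' 1000-tree random forest with importance; `GBM` depth-2 bernoulli
#' gradient boosting with the tree count chosen by cross-validation;
#' `XGBoost` binary-logistic boosting with the round count chosen by
#' 5-fold CV and early stopping; `LDA` and Gaussian `NaiveBayes` are
#' standard.
#'
#' @param spec a [learner_spec()].
#' @param X samples x features numeric matrix (>= 2 features, no NA).
#' @param y 0/1 numeric or `Control`/`Treat` labels, both classes present.
#' @param seed integer seed.
#' @return a fitted `mitodx_learner`.
#' @export
fit_learner <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "mitodx_learner_spec"))
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("y has a single class; cannot fit")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need >= 2 features")
  if (anyNA(X)) stop("X contains missing values")
  set.seed(seed)
  fit <- switch(spec$algorithm,
    Lasso = , Ridge = , Enet = fit_glmnet_learner(X, y, spec$alpha),
    StepGLM = fit_stepglm_learner(X, y, spec$direction),
    SVM = fit_svm_learner(X, y),
    GlmBoost = fit_glmboost(X, y, nu = 0.1, mstop_max = 1000, nfolds = 10),
    LDA = fit_lda_learner(X, y),
    PlsRglm = fit_plsglm(X, y, ncomp_max = 5, nfolds = 10),
    RF = fit_rf_learner(X, y),
    GBM = fit_gbm(X, y, n_trees = 500, shrinkage = 0.1, depth = 2, nfolds = 10),
    XGBoost = fit_xgb_learner(X, y),
    NaiveBayes = fit_nb_learner(X, y)
  )
  structure(list(spec = spec, model = fit, features = colnames(X), seed = seed),
            class = "mitodx_learner")
}

#' Positive-class probabilities from a fitted learner
#'
#' @param fit a `mitodx_learner`.
#' @param X samples x features matrix covering the training features.
#' @return numeric probabilities of the `Treat` class in `[0, 1]`.
#' @export
predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "mitodx_learner"))
  missing <- setdiff(fit$features, colnames(X))
  if (length(missing)) {
    stop("prediction matrix lacks features: ", paste(head(missing, 5), collapse = ", "))
  }
  X <- X[, fit$features, drop = FALSE]
  p <- fit$model$predict(X)
  pmin(pmax(as.vector(p), 0), 1)
}

#' Features surviving a fitted learner (the "subFeature" contract)
#'
#' Penalized GLMs, componentwise boosting and PLS logistic drop
#' zero-coefficient variables; stepwise regression returns the variables
#' entering the final model; random forest and GBM keep variables with
#' relative importance > 0; SVM, LDA, XGBoost and NaiveBayes return all
#' features (as does Ridge, whose coefficients are never exactly zero).
#'
#' @param fit a `mitodx_learner`.
#' @return character vector of selected feature names.
#' @export
extract_features <- function(fit) {
  if (!inherits(fit, "mitodx_learner")) stop("learner is not fitted")
  sel <- fit$model$selected
  if (is.null(sel)) fit$features else sel
}

# --- individual learner backends -------------------------------------------
# Each backend returns list(predict = function(X) prob, selected = chr|NULL,
# ...extras). selected == NULL means "all features".

fit_glmnet_learner <- function(X, y, alpha) {
  nfolds <- min(10, max(3, min(table(y))))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                          nfolds = nfolds, type.measure = "deviance")
  beta <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  selected <- if (alpha > 0) names(beta)[beta != 0] else NULL
  list(
    predict = function(Xn) {
      as.vector(predict(cv, newx = Xn, s = "lambda.min", type = "response"))
    },
    selected = selected, coef = beta, lambda = cv$lambda.min
  )
}

fit_stepglm_learner <- function(X, y, direction) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  full_formula <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  model <- tryCatch({
    suppressWarnings({
      if (direction == "forward") {
        start <- glm(.y ~ 1, data = df, family = binomial())
        MASS::stepAIC(start, scope = list(lower = ~1, upper = full_formula[-2]),
                      direction = "forward", trace = 0)
      } else {
        start <- glm(full_formula, data = df, family = binomial())
        MASS::stepAIC(start, direction = direction, trace = 0)
      }
    })
  }, error = function(e) NULL)
  if (is.null(model)) {
    # separation-guard fallback: ridge-stabilized logistic fit on all terms
    warning("stepwise fit failed (likely separation); ridge-stabilized fallback")
    rg <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1e-3)
    return(list(
      predict = function(Xn) {
        as.vector(predict(rg, newx = Xn, type = "response"))
      },
      selected = colnames(X), fallback = TRUE
    ))
  }
  terms_in <- attr(terms(model), "term.labels")
  selected <- gsub("^`|`$", "", terms_in)
  list(
    predict = function(Xn) {
      nd <- as.data.frame(Xn, check.names = FALSE)
      suppressWarnings(as.vector(predict(model, newdata = nd, type = "response")))
    },
    selected = selected, model = model
  )
}

fit_svm_learner <- function(X, y) {
  yf <- factor(ifelse(y == 1, "Treat", "Control"), levels = c("Control", "Treat"))
  model <- e1071::svm(X, yf, kernel = "radial", cost = 1, gamma = 1 / ncol(X),
                      probability = TRUE)
  list(
    predict = function(Xn) {
      pr <- predict(model, Xn, probability = TRUE)
      attr(pr, "probabilities")[, "Treat"]
    },
    selected = NULL, model = model
  )
}

fit_lda_learner <- function(X, y) {
  yf <- factor(ifelse(y == 1, "Treat", "Control"), levels = c("Control", "Treat"))
  model <- MASS::lda(X, grouping = yf)
  list(
    predict = function(Xn) predict(model, Xn)$posterior[, "Treat"],
    selected = NULL, model = model
  )
}

fit_nb_learner <- function(X, y) {
  yf <- factor(ifelse(y == 1, "Treat", "Control"), levels = c("Control", "Treat"))
  model <- e1071::naiveBayes(X, yf)
  list(
    predict = function(Xn) {
      suppressWarnings(predict(model, Xn, type = "raw")[, "Treat"])
    },
    selected = NULL, model = model
  )
}

fit_rf_learner <- function(X, y) {
  yf <- factor(ifelse(y == 1, "Treat", "Control"), levels = c("Control", "Treat"))
  model <- randomForest::randomForest(X, yf, ntree = 1000, importance = TRUE)
  imp <- randomForest::importance(model, type = 2)[, 1]  # mean Gini decrease
  list(
    predict = function(Xn) predict(model, Xn, type = "prob")[, "Treat"],
    selected = names(imp)[imp > 0], importance = imp, model = model
  )
}

fit_xgb_learner <- function(X, y) {
  params <- list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                 nthread = 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = 500,
                        nfold = 5, early_stopping_rounds = 25, verbose = 0)
  best <- cv$early_stop$best_iteration %||% cv$best_iteration %||% cv$niter
  model <- xgboost::xgb.train(params = params, data = dtrain, nrounds = best,
                              verbose = 0)
  list(
    predict = function(Xn) predict(model, xgboost::xgb.DMatrix(Xn)),
    selected = NULL, model = model, nrounds = best
  )
}
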