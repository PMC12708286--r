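# Componentwise gradient boosting of the logistic loss (linear base
# learners). Each iteration fits every centred covariate (plus an
# intercept learner) to the negative gradient by least squares, updates
# only the best-fitting one by a step of length nu, and the stopping
# iteration is chosen by cross-validated predictive deviance. With a
# single covariate and a large stopping iteration this converges to the
# unpenalized logistic MLE.

glmboost_path <- function(Xc, y, nu, mstop) {
  n <- nrow(Xc); p <- ncol(Xc)
  ss <- colSums(Xc^2)
  active <- ss > 0
  f <- rep(0, n)
  beta0 <- 0
  beta <- numeric(p)
  sel_count <- integer(p)
  path_beta0 <- numeric(mstop)
  path_beta <- matrix(0, mstop, p)
  for (m in seq_len(mstop)) {
    u <- y - plogis(f)
    b_int <- mean(u)
    gain_int <- n * b_int^2
    b <- rep(0, p)
    b[active] <- colSums(Xc[, active, drop = FALSE] * u) / ss[active]
    gain <- b^2 * ss
    j <- which.max(gain)
    if (gain_int >= gain[j]) {
      beta0 <- beta0 + nu * b_int
      f <- f + nu * b_int
    } else {
      beta[j] <- beta[j] + nu * b[j]
      sel_count[j] <- sel_count[j] + 1L
      f <- f + nu * b[j] * Xc[, j]
    }
    path_beta0[m] <- beta0
    path_beta[m, ] <- beta
  }
  list(beta0 = path_beta0, beta = path_beta)
}

fit_glmboost <- function(X, y, nu = 0.1, mstop_max = 1000, nfolds = 10) {
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  n <- nrow(X)
  nfolds <- min(nfolds, n)
  folds <- make_cv_folds(y, nfolds)
  risk <- matrix(0, mstop_max, length(folds))
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    path <- glmboost_path(Xc[-test, , drop = FALSE], y[-test], nu, mstop_max)
    eta <- Xc[test, , drop = FALSE] %*% t(path$beta)   # n_test x mstop
    eta <- sweep(eta, 2, path$beta0, `+`)
    pr <- plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    risk[, fi] <- -colMeans(y[test] * log(pr) + (1 - y[test]) * log(1 - pr))
  }
  mstop <- which.min(rowMeans(risk))
  path <- glmboost_path(Xc, y, nu, mstop)
  beta <- path$beta[mstop, ]
  beta0 <- path$beta0[mstop]
  names(beta) <- colnames(X)
  list(
    predict = function(Xn) {
      as.vector(plogis(beta0 + sweep(Xn, 2, centers) %*% beta))
    },
    selected = names(beta)[beta != 0],
    coef = beta, intercept = beta0, mstop = mstop
  )
}

# Stratified cross-validation folds (list of test-index vectors); keeps
# both classes in every training split whenever possible.
make_cv_folds <- function(y, nfolds) {
  idx0 <- sample(which(y == 0))
  idx1 <- sample(which(y == 1))
  assign_folds <- function(idx) {
    if (!length(idx)) return(integer(0))
    rep_len(seq_len(nfolds), length(idx))
  }
  fold_of <- integer(length(y))
  fold_of[idx0] <- assign_folds(idx0)
  fold_of[idx1] <- assign_folds(idx1)
  out <- split(seq_along(y), fold_of)
  out[vapply(out, length, 1L) > 0]
}

# Gradient boosting with depth-limited regression trees on the bernoulli
# (logistic) loss: trees are fitted to the gradient residual y - p and
# terminal-node values use the one-step Newton update. Relative variable
# importance is the summed split improvement per variable across trees.

fit_gbm_trees <- function(df, y, n_trees, shrinkage, depth) {
  n <- nrow(df)
  pbar <- mean(y)
  f0 <- log(pbar / (1 - pbar))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  control <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 10,
                                  minbucket = 5, xval = 0, maxcompete = 0,
                                  maxsurrogate = 0, usesurrogate = 0)
  for (m in seq_len(n_trees)) {
    p <- plogis(f)
    df$.z <- y - p
    tree <- rpart::rpart(.z ~ ., data = df, method = "anova", control = control)
    leaf <- tree$where
    hess <- p * (1 - p)
    num <- tapply(df$.z, leaf, sum)
    den <- tapply(hess, leaf, sum)
    gamma <- setNames(as.vector(num / pmax(den, 1e-12)), names(num))
    # store the Newton leaf values in the tree so predict() returns them
    leaf_rows <- as.integer(names(gamma))
    tree$frame$yval[leaf_rows] <- gamma
    f <- f + shrinkage * unname(gamma[as.character(leaf)])
    keep <- c("frame", "splits", "csplit", "where", "terms", "control",
              "method", "functions", "ordered")
    tree_small <- tree[intersect(keep, names(tree))]
    class(tree_small) <- "rpart"
    attr(tree_small, "xlevels") <- attr(tree, "xlevels")
    trees[[m]] <- tree_small
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

gbm_predict_path <- function(model, newdata, n_trees = length(model$trees)) {
  f <- matrix(model$f0, nrow(newdata), n_trees)
  acc <- rep(model$f0, nrow(newdata))
  for (m in seq_len(n_trees)) {
    acc <- acc + model$shrinkage * predict(model$trees[[m]], newdata = newdata)
    f[, m] <- acc
  }
  f
}

fit_gbm <- function(X, y, n_trees = 500, shrinkage = 0.1, depth = 2,
                    nfolds = 10) {
  df <- as.data.frame(X)
  colnames(df) <- make.names(colnames(X), unique = TRUE)
  name_map <- setNames(colnames(X), colnames(df))
  nfolds <- min(nfolds, nrow(X))
  folds <- make_cv_folds(y, nfolds)
  risk <- matrix(0, n_trees, length(folds))
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    model <- fit_gbm_trees(df[-test, , drop = FALSE], y[-test], n_trees,
                           shrinkage, depth)
    path <- gbm_predict_path(model, df[test, , drop = FALSE])
    pr <- pmin(pmax(plogis(path), 1e-12), 1 - 1e-12)
    risk[, fi] <- -colMeans(y[test] * log(pr) + (1 - y[test]) * log(1 - pr))
  }
  best <- which.min(rowMeans(risk))
  model <- fit_gbm_trees(df, y, best, shrinkage, depth)
  imp_safe <- numeric(length(name_map))
  names(imp_safe) <- names(name_map)
  for (tree in model$trees) {
    if (!is.null(tree$splits) && nrow(tree$splits)) {
      sp <- tree$splits
      vars <- rownames(sp)
      for (i in seq_len(nrow(sp))) {
        imp_safe[vars[i]] <- imp_safe[vars[i]] + sp[i, "improve"]
      }
    }
  }
  importance <- setNames(as.numeric(imp_safe), name_map[names(imp_safe)])
  list(
    predict = function(Xn) {
      nd <- as.data.frame(Xn)
      colnames(nd) <- names(name_map)[match(colnames(Xn), name_map)]
      f <- gbm_predict_path(model, nd)[, length(model$trees)]
      plogis(f)
    },
    selected = unname(name_map[names(imp_safe)[imp_safe > 0]]),
    importance = importance, n_trees = best, model = model
  )
}
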