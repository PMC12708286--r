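# Logistic regression on partial-least-squares components ("PLS-GLM
# logistic"). Components are extracted by NIPALS PLS1 on the
# standardized predictors against the centred 0/1 response; a binomial
# GLM is then fitted on the component scores. The component count is
# chosen by cross-validated misclassification (smallest count on ties,
# capped at ncomp_max). In the sparse reading of the model, features
# whose back-transformed coefficient magnitude is below 1e-8 are dropped
# from the selected set.

pls_components <- function(Xs, y, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp <- min(ncomp, p, n - 1)
  E <- Xs
  fvec <- y - mean(y)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  kept <- 0
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, fvec)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_score <- E %*% w
    tt <- sum(t_score^2)
    if (tt < 1e-12) break
    p_load <- crossprod(E, t_score) / tt
    q <- sum(fvec * t_score) / tt
    E <- E - t_score %*% t(p_load)
    fvec <- fvec - q * t_score
    kept <- a
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_score
  }
  if (kept == 0) stop("no informative PLS component could be extracted")
  W <- W[, seq_len(kept), drop = FALSE]
  P <- P[, seq_len(kept), drop = FALSE]
  Tm <- Tm[, seq_len(kept), drop = FALSE]
  # rotation mapping standardized X to scores: T = Xs %*% R
  R <- W %*% solve(crossprod(P, W))
  list(T = Tm, R = R, ncomp = kept)
}

plsglm_core <- function(Xs, y, ncomp) {
  pc <- pls_components(Xs, y, ncomp)
  df <- data.frame(.y = y, pc$T)
  model <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  q <- coef(model)
  q[is.na(q)] <- 0
  beta <- as.vector(pc$R %*% q[-1])
  list(intercept = q[1], beta = beta, ncomp = pc$ncomp)
}

fit_plsglm <- function(X, y, ncomp_max = 5, nfolds = 10) {
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  scales[scales == 0] <- 1
  Xs <- scale(X, center = centers, scale = scales)
  nfolds <- min(nfolds, nrow(X))
  folds <- make_cv_folds(y, nfolds)
  ncomp_max <- min(ncomp_max, ncol(X), nrow(X) - 2)
  miss <- matrix(NA_real_, ncomp_max, length(folds))
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    for (nc in seq_len(ncomp_max)) {
      fitc <- tryCatch(plsglm_core(Xs[-test, , drop = FALSE], y[-test], nc),
                       error = function(e) NULL)
      if (is.null(fitc)) next
      eta <- fitc$intercept + Xs[test, , drop = FALSE] %*% fitc$beta
      miss[nc, fi] <- mean((plogis(eta) >= 0.5) != (y[test] == 1))
    }
  }
  mean_miss <- rowMeans(miss, na.rm = TRUE)
  mean_miss[!is.finite(mean_miss)] <- Inf
  ncomp <- which.min(mean_miss)  # smallest count wins ties
  fit <- plsglm_core(Xs, y, ncomp)
  beta <- setNames(fit$beta, colnames(X))
  list(
    predict = function(Xn) {
      Xsn <- scale(Xn, center = centers, scale = scales)
      as.vector(plogis(fit$intercept + Xsn %*% beta))
    },
    selected = names(beta)[abs(beta) > 1e-8],
    coef = beta, intercept = fit$intercept, ncomp = fit$ncomp
  )
}
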