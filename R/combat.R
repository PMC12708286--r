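#' Empirical-Bayes location-scale batch correction
#'
#' Parametric empirical-Bayes adjustment of per-batch gene-wise means and
#' variances, protecting a biological group covariate. Each gene is
#' standardized against a model containing an intercept, batch indicators
#' and the group covariate; per-batch location and scale estimates are
#' shrunk towards their across-gene priors (normal prior on the location,
#' inverse-gamma on the scale) by the iterative joint update, and the data
#' are back-transformed.
#'
#' @param matrix genes x samples matrix (log2 scale).
#' @param batch character/factor vector of batch labels per sample
#'   (>= 2 batches, each with >= 2 samples).
#' @param group optional character/factor of the protected biological
#'   covariate (e.g. `Control`/`Treat`); must not be confounded 1:1 with
#'   batch.
#' @param tol convergence tolerance for the EB update (default 1e-4).
#' @param max_iter iteration cap (default 100).
#' @return adjusted matrix with identical dimensions.
#' @export
combat_adjust <- function(matrix, batch, group = NULL, tol = 1e-4, max_iter = 100) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(matrix)
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("every batch needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  n <- ncol(matrix)
  n_batch <- nlevels(batch)
  batches <- lapply(levels(batch), function(b) which(batch == b))
  n_b <- vapply(batches, length, 1L)

  design <- model.matrix(~ 0 + batch)  # cell-means batch design
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) > 1) {
      design <- cbind(design, model.matrix(~group)[, -1, drop = FALSE])
    }
  }
  if (qr(design)$rank < ncol(design)) {
    stop("group covariate is confounded with batch; design is not estimable")
  }

  # gene-wise least squares for batch means + covariate effects
  B_hat <- solve(crossprod(design), crossprod(design, t(matrix)))  # p x genes
  grand_mean <- crossprod(n_b / n, B_hat[seq_len(n_batch), , drop = FALSE])
  stand_mean <- matrix(grand_mean, nrow(matrix), n)  # genes x samples
  if (ncol(design) > n_batch) {
    covar <- design[, -seq_len(n_batch), drop = FALSE]
    stand_mean <- stand_mean +
      t(covar %*% B_hat[-seq_len(n_batch), , drop = FALSE])
  }
  resid <- matrix - t(design %*% B_hat)
  var_pooled <- rowSums(resid^2) / n
  if (any(var_pooled == 0)) {
    stop("gene(s) with zero pooled variance; filter constant genes first")
  }
  z <- (matrix - stand_mean) / sqrt(var_pooled)

  adjusted <- z
  for (bi in seq_len(n_batch)) {
    idx <- batches[[bi]]
    zb <- z[, idx, drop = FALSE]
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1, var)
    # priors by moment matching across genes
    gamma_bar <- mean(gamma_hat)
    tau2 <- var(gamma_hat)
    m <- mean(delta_hat); v <- var(delta_hat)
    a_prior <- (2 * v + m^2) / v
    b_prior <- (m * v + m^3) / v
    nb <- length(idx)
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    change <- 1
    iter <- 0
    while (change > tol && iter < max_iter) {
      g_new <- (nb * tau2 * gamma_hat + delta_star * gamma_bar) /
        (nb * tau2 + delta_star)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - gamma_star) / abs(gamma_star),
                    abs(d_new - delta_star) / delta_star)
      gamma_star <- g_new
      delta_star <- d_new
      iter <- iter + 1
    }
    adjusted[, idx] <- (zb - gamma_star) / sqrt(delta_star)
  }
  out <- adjusted * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(matrix)
  out
}
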