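#' Gene-wise two-group linear fit
#'
#' Per gene: the Treat-minus-Control difference of means (log2 fold
#' change), the pooled residual variance and its degrees of freedom.
#'
#' @param matrix genes x samples log2 matrix.
#' @param groups character/factor per sample with levels containing
#'   `Control` and `Treat`; each group needs >= 2 samples.
#' @return data.frame with `gene`, `log2FC`, `ave_expr`, `s2`,
#'   `df_residual`, plus attributes `n1` (Control) and `n2` (Treat).
#' @export
fit_two_group <- function(matrix, groups) {
  groups <- as.character(groups)
  i1 <- which(groups == "Control")
  i2 <- which(groups == "Treat")
  if (length(i1) < 2 || length(i2) < 2) {
    stop("both groups need >= 2 samples")
  }
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  ss1 <- rowSums((matrix[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((matrix[, i2, drop = FALSE] - m2)^2)
  df <- length(i1) + length(i2) - 2L
  out <- data.frame(
    gene = rownames(matrix),
    log2FC = m2 - m1,
    ave_expr = rowMeans(matrix[, c(i1, i2), drop = FALSE]),
    s2 = (ss1 + ss2) / df,
    df_residual = df,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n1") <- length(i1)
  attr(out, "n2") <- length(i2)
  out
}

# Invert the trigamma function by Newton iteration on 1/x scale
# (monotone, converges in a handful of steps for y > 0).
trigamma_inverse <- function(y) {
  out <- y
  pos <- which(is.finite(y) & y > 0)
  x <- 0.5 + 1 / y[pos]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[pos]) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  out[pos] <- x
  out
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Matches the mean and variance of `log(s2)` against the scaled-F
#' sampling model to obtain prior degrees of freedom `d0` and prior
#' variance `s0_2`. If the spread of `log(s2)` does not exceed its
#' sampling component, `d0` is infinite (complete pooling).
#'
#' @param s2 gene-wise residual variances (> 0, length >= 10).
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0` and `s0_2`.
#' @export
estimate_variance_prior <- function(s2, df) {
  if (length(s2) < 10) stop("moment estimation needs >= 10 genes")
  if (all(s2 == s2[1]) && s2[1] == 0) stop("all residual variances are zero")
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: complete pooling
    return(list(d0 = Inf, s0_2 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics by empirical-Bayes variance shrinkage
#'
#' Shrinks each gene's variance towards the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d\,s^2)/(d_0 + d)}, forms
#' \eqn{t = \mathrm{log2FC} / (\tilde s \sqrt{1/n_1 + 1/n_2})} and
#' two-sided p-values on \eqn{d_0 + d} degrees of freedom (normal tails
#' when \eqn{d_0 = \infty}).
#'
#' @param fit output of [fit_two_group()].
#' @return the table with added `t_mod`, `p`, `p_adj` columns and
#'   attributes `d0`, `s0_2`.
#' @export
ebayes_moderate <- function(fit) {
  n1 <- attr(fit, "n1"); n2 <- attr(fit, "n2")
  if (is.null(n1) || is.null(n2)) stop("fit must come from fit_two_group()")
  prior <- estimate_variance_prior(fit$s2, fit$df_residual[1])
  d0 <- prior$d0; s0_2 <- prior$s0_2
  df <- fit$df_residual
  s2_post <- if (is.infinite(d0)) rep(s0_2, nrow(fit)) else {
    (d0 * s0_2 + df * fit$s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- fit$log2FC / se
  # with an infinite prior the reference t uses the pooled residual df
  # (practically normal tails)
  df_total <- if (is.infinite(d0)) sum(df) else d0 + df
  p <- 2 * pt(-abs(t_mod), df = df_total)
  fit$t_mod <- t_mod
  fit$p <- p
  fit$p_adj <- bh_adjust(p)
  attr(fit, "d0") <- d0
  attr(fit, "s0_2") <- s0_2
  fit
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Filter differentially expressed genes
#'
#' Strict thresholds on adjusted p and absolute log2 fold change, split
#' by direction.
#'
#' @param table output of [ebayes_moderate()].
#' @param lfc_min minimum absolute log2 fold change (strict `>`).
#' @param fdr maximum adjusted p (strict `<`).
#' @return list with `up` and `down` character vectors of gene symbols
#'   (sorted).
#' @export
filter_degs <- function(table, lfc_min = 1.5, fdr = 0.05) {
  sig <- table$p_adj < fdr
  list(
    up = sort(table$gene[sig & table$log2FC > lfc_min]),
    down = sort(table$gene[sig & table$log2FC < -lfc_min])
  )
}

#' Run the full two-group differential expression stage
#'
#' @inheritParams fit_two_group
#' @inheritParams filter_degs
#' @return list with the complete `table` and the `up`/`down` gene sets.
#' @export
run_dge <- function(matrix, groups, lfc_min = 1.5, fdr = 0.05) {
  table <- ebayes_moderate(fit_two_group(matrix, groups))
  c(list(table = table), filter_degs(table, lfc_min, fdr))
}
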