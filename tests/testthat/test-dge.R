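toy_fit <- function() {
  m <- rbind(
    gA = c(1, 2, 3, 5, 6, 7),
    gB = c(4, 4, 4, 4, 4, 4) + c(0.1, -0.1, 0, 0.1, -0.1, 0),
    gC = c(2, 3, 4, 2, 3, 4)
  )
  colnames(m) <- sprintf("s%d", 1:6)
  groups <- rep(c("Control", "Treat"), each = 3)
  list(m = m, groups = groups)
}

test_that("two-group fit matches textbook pooled statistics", {
  t <- toy_fit()
  fit <- fit_two_group(t$m, t$groups)
  expect_equal(fit$log2FC[1], 4)            # mean(5,6,7) - mean(1,2,3)
  expect_equal(fit$log2FC[3], 0)            # identical group means
  s2_hand <- (sum((c(1, 2, 3) - 2)^2) + sum((c(5, 6, 7) - 6)^2)) / 4
  expect_equal(fit$s2[1], s2_hand)
  expect_equal(fit$df_residual[1], 4)
  expect_error(fit_two_group(t$m, c("Control", rep("Treat", 5))), ">= 2")
})

test_that("planted log2 fold changes are estimated without bias", {
  sim <- simulate_cohorts(sim_config(
    n_cohorts = 1, n_control = 40, n_treat = 40, n_genes = 500,
    module_sizes = integer(0), n_de_genes = 100, delta = 2, noise_sd = 1,
    batch_shift_sd = 0, seed = 17
  ))
  fit <- fit_two_group(sim$matrices[[1]],
                       setNames(sim$pheno$group, sim$pheno$sample_id))
  est <- mean(fit$log2FC[fit$gene %in% sim$truth$de_genes])
  expect_lt(abs(est - 2), 0.2)
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  set.seed(23)
  m <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:20)))
  g1 <- rep(c("Control", "Treat"), each = 10)
  g2 <- rep(c("Treat", "Control"), each = 10)
  a <- ebayes_moderate(fit_two_group(m, g1))
  b <- ebayes_moderate(fit_two_group(m, g2))
  expect_equal(a$log2FC, -b$log2FC)
  expect_equal(a$p, b$p)
})

test_that("moderated t interpolates between ordinary t and pooled z", {
  set.seed(31)
  m <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:12)))
  groups <- rep(c("Control", "Treat"), each = 6)
  fit <- fit_two_group(m, groups)
  eb <- ebayes_moderate(fit)
  se_factor <- sqrt(1 / 6 + 1 / 6)
  t_ord <- fit$log2FC / sqrt(fit$s2 * se_factor^2)
  t_pool <- fit$log2FC / sqrt(attr(eb, "s0_2") * se_factor^2)
  lo <- pmin(t_ord, t_pool) - 1e-12
  hi <- pmax(t_ord, t_pool) + 1e-12
  expect_true(all(eb$t_mod >= lo & eb$t_mod <= hi))
})

test_that("with equal variances the moderated t degenerates to a z-statistic", {
  set.seed(37)
  m <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:10)))
  groups <- rep(c("Control", "Treat"), each = 5)
  fit <- fit_two_group(m, groups)
  fit$s2 <- rep(2, nrow(fit))  # inject identical variances: d0 -> Inf
  eb <- ebayes_moderate(fit)
  expect_true(is.infinite(attr(eb, "d0")))
  z <- fit$log2FC / sqrt(attr(eb, "s0_2") * (1 / 5 + 1 / 5))
  expect_equal(eb$t_mod, z)
  # pooled df are large enough that tails are effectively normal
  expect_equal(eb$p, 2 * pnorm(-abs(z)), tolerance = 1e-2)
})

test_that("with wildly heterogeneous variances moderation approaches the plain t", {
  set.seed(41)
  n_genes <- 400
  sds <- exp(runif(n_genes, -2, 2))  # wide spread drives d0 below 1
  m <- matrix(rnorm(n_genes * 16), n_genes, 16) * sds
  dimnames(m) <- list(sprintf("g%d", 1:n_genes), sprintf("s%d", 1:16))
  groups <- rep(c("Control", "Treat"), each = 8)
  fit <- fit_two_group(m, groups)
  eb <- ebayes_moderate(fit)
  t_plain <- apply(m, 1, function(x) {
    t.test(x[groups == "Treat"], x[groups == "Control"],
           var.equal = TRUE)$statistic
  })
  expect_gt(cor(eb$t_mod, t_plain), 0.99)
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(43)
  m <- matrix(rnorm(300 * 20, 8, 1), 300, 20,
              dimnames = list(sprintf("g%d", 1:300), sprintf("s%d", 1:20)))
  m[1:30, 11:20] <- m[1:30, 11:20] + 1.5
  groups <- rep(c("Control", "Treat"), each = 10)
  eb <- ebayes_moderate(fit_two_group(m, groups))
  design <- model.matrix(~factor(groups, levels = c("Control", "Treat")))
  ref <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(eb, "d0"), ref$df.prior, tolerance = 1e-6)
  expect_equal(attr(eb, "s0_2"), ref$s2.prior, tolerance = 1e-6)
  expect_equal(eb$t_mod, unname(ref$t[, 2]), tolerance = 1e-10)
  expect_equal(eb$p, unname(ref$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment reproduces hand arithmetic and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))  # base-R cross-check
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG filtering applies strict thresholds by direction", {
  tbl <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2FC = c(1.5, 2, -2, 2),
    p_adj = c(0.01, 0.01, 0.01, 0.05)
  )
  res <- filter_degs(tbl)
  expect_equal(res$up, "b")     # 1.5 exactly excluded; 0.05 exactly excluded
  expect_equal(res$down, "c")
})

test_that("planted DE genes are recovered with high sensitivity", {
  sim <- simulate_cohorts(sim_config(
    n_cohorts = 1, n_control = 40, n_treat = 40, n_genes = 1000,
    module_sizes = c(100), n_de_genes = 100, delta = 2, noise_sd = 0.5,
    seed = 47
  ))
  d <- run_dge(sim$matrices[[1]],
               setNames(sim$pheno$group, sim$pheno$sample_id))
  sens <- mean(sim$truth$de_genes %in% union(d$up, d$down))
  expect_gte(sens, 0.9)
})

test_that("BH keeps empirical FDR near its nominal level", {
  set.seed(53)
  fdrs <- replicate(20, {
    n_genes <- 400; n_de <- 60
    m <- matrix(rnorm(n_genes * 30), n_genes, 30)
    m[seq_len(n_de), 16:30] <- m[seq_len(n_de), 16:30] + 1.5
    dimnames(m) <- list(sprintf("g%d", seq_len(n_genes)), sprintf("s%d", 1:30))
    d <- run_dge(m, rep(c("Control", "Treat"), each = 15), lfc_min = 0)
    hits <- union(d$up, d$down)
    if (!length(hits)) return(0)
    mean(!hits %in% sprintf("g%d", seq_len(n_de)))
  })
  expect_lte(mean(fdrs), 0.05 + 0.02)
})
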