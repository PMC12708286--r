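test_that("invalid simulator configurations are rejected naming the field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(module_sizes = c(500, 600), n_genes = 1000),
               "module_sizes")
  expect_error(sim_config(n_de_genes = 50, n_genes = 40,
                          module_sizes = integer(0)), "n_de_genes")
  expect_error(sim_config(batch_scale_range = c(2, 1)), "batch_scale_range")
})

test_that("identical configuration and seed give byte-identical bundles", {
  cfg <- sim_config(n_cohorts = 2, n_genes = 200, module_sizes = c(60),
                    n_de_genes = 20, missing_rate = 0.05, seed = 42)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a, b)
  d <- simulate_cohorts(sim_config(n_cohorts = 2, n_genes = 200,
                                   module_sizes = c(60), n_de_genes = 20,
                                   missing_rate = 0.05, seed = 43))
  expect_false(identical(a$matrices, d$matrices))
})

test_that("truth bundle is internally consistent", {
  cfg <- sim_config(n_cohorts = 2, n_genes = 500, module_sizes = c(100, 60),
                    n_de_genes = 50, mito_fraction = 0.2, seed = 7)
  sim <- simulate_cohorts(cfg)
  genes <- rownames(sim$matrices[[1]])
  expect_true(all(sim$truth$de_genes %in% genes))
  expect_true(all(sim$truth$mito_genes %in% genes))
  expect_equal(length(sim$truth$mito_genes), 100)
  expect_true(all(sim$truth$module_assignment %in% 0:2))
  expect_equal(sum(sim$truth$module_assignment == 1), 100)
  expect_equal(nrow(sim$pheno), 2 * 40)
  expect_setequal(unique(sim$pheno$group), c("Control", "Treat"))
  # DE genes over-represented in the mitochondrial subset by construction
  de_rate_mito <- mean(sim$truth$mito_genes %in% sim$truth$de_genes)
  de_rate_all <- length(sim$truth$de_genes) / length(genes)
  expect_gt(de_rate_mito, de_rate_all)
})

test_that("with no planted effect two-group t-test p-values are uniform", {
  sim <- simulate_cohorts(sim_config(
    n_cohorts = 1, n_genes = 2000, module_sizes = integer(0),
    n_de_genes = 0, delta = 0, missing_rate = 0, seed = 11
  ))
  m <- sim$matrices[[1]]
  grp <- sim$pheno$group
  p <- apply(m, 1, function(x) t.test(x[grp == "Treat"], x[grp == "Control"],
                                      var.equal = TRUE)$p.value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DEG pass fraction matches a Monte-Carlo oracle on the same normal model", {
  # oracle: plain two-sample t-tests on data drawn directly from the
  # N(mu, noise^2) (+delta for DE genes) model, thresholded exactly as the
  # pipeline thresholds
  n_genes <- 1000; n_de <- 250; n <- 20; delta <- 2; noise <- 1
  oracle_fraction <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(n_genes * 2 * n, 0, noise), n_genes, 2 * n)
    treat <- (n + 1):(2 * n)
    x[seq_len(n_de), treat] <- x[seq_len(n_de), treat] + delta
    p <- apply(x, 1, function(v) t.test(v[treat], v[-treat],
                                        var.equal = TRUE)$p.value)
    lfc <- rowMeans(x[, treat]) - rowMeans(x[, -treat])
    padj <- p.adjust(p, "BH")
    mean(padj[seq_len(n_de)] < 0.05 & abs(lfc[seq_len(n_de)]) > 1.5)
  }
  oracle <- mean(vapply(1:10, oracle_fraction, 1))

  sim_fraction <- function(seed) {
    sim <- simulate_cohorts(sim_config(
      n_cohorts = 1, n_genes = n_genes, module_sizes = integer(0),
      n_de_genes = n_de, delta = delta, noise_sd = noise,
      batch_shift_sd = 0, batch_scale_range = c(1, 1), seed = seed
    ))
    d <- run_dge(sim$matrices[[1]],
                 setNames(sim$pheno$group, sim$pheno$sample_id))
    mean(sim$truth$de_genes %in% union(d$up, d$down))
  }
  observed <- mean(vapply(101:105, sim_fraction, 1))
  expect_lt(abs(observed - oracle), 0.03)
})

test_that("probe expansion annotates and round-trips correctly", {
  sim <- simulate_cohorts(sim_config(n_cohorts = 1, n_genes = 50,
                                     module_sizes = integer(0),
                                     n_de_genes = 0, seed = 3))
  m <- sim$matrices[[1]]
  one <- expand_to_probes(m, probes_per_gene = 1, probe_offset_sd = 0, seed = 5)
  expect_equal(nrow(one$annotation), 50)
  expect_false(anyDuplicated(one$annotation$gene_symbol) > 0)  # bijection
  expect_true(all(one$annotation$status == "mapped"))

  two <- expand_to_probes(m, probes_per_gene = 2, probe_offset_sd = 0, seed = 5)
  collapsed <- collapse_probes(two$probe_matrix, two$annotation)
  expect_equal(collapsed, m[sort(rownames(m)), ])  # exact round trip

  amb <- expand_to_probes(m, probes_per_gene = 1, frac_ambiguous = 0.1, seed = 5)
  expect_equal(sum(amb$annotation$status == "ambiguous"), 5)
  kept <- collapse_probes(amb$probe_matrix, amb$annotation)
  dropped <- amb$annotation$gene_symbol[amb$annotation$status == "ambiguous"]
  expect_setequal(setdiff(rownames(m), rownames(kept)), dropped)
})

test_that("missingness injection hits the requested rate reproducibly", {
  m <- matrix(rnorm(10000), 100, 100)
  expect_identical(inject_missing(m, 0), m)
  a <- inject_missing(m, 0.05, seed = 9)
  b <- inject_missing(m, 0.05, seed = 9)
  expect_identical(which(is.na(a)), which(is.na(b)))
  expect_true(abs(sum(is.na(a)) - 500) <= 70)  # binomial 99% interval
  expect_error(inject_missing(m, 1), "missing_rate")
})

test_that("raw-scale output triggers the log2 rule while log-scale does not", {
  cfg_raw <- sim_config(n_cohorts = 1, n_genes = 300, module_sizes = integer(0),
                        n_de_genes = 0, raw_scale = TRUE, seed = 13)
  raw <- simulate_cohorts(cfg_raw)$matrices[[1]]
  expect_true(auto_log2(raw)$applied)
  cfg_log <- sim_config(n_cohorts = 1, n_genes = 300, module_sizes = integer(0),
                        n_de_genes = 0, raw_scale = FALSE, seed = 13)
  logm <- simulate_cohorts(cfg_log)$matrices[[1]]
  expect_false(auto_log2(logm)$applied)
})
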