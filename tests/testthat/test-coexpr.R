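test_that("variance filter keeps strictly variable genes", {
  x <- rep(c(0, 1), 5)
  m <- rbind(const = rep(5, 10),
             exact = x * (0.5 / sd(x)),  # sd exactly 0.5
             wide = as.numeric(seq(0, 9)))
  colnames(m) <- sprintf("s%d", 1:10)
  out <- filter_variable_genes(m, 0.5)
  expect_equal(rownames(out), "wide")  # constant dropped, sd==0.5 dropped

  set.seed(1)
  sds <- c(0.2, 0.6, 1.1, 0.5)
  m2 <- t(sapply(sds, function(s) { v <- rnorm(20); v / sd(v) * s }))
  rownames(m2) <- sprintf("g%d", 1:4)
  expect_equal(nrow(filter_variable_genes(m2, 0.5)), 2)
})

test_that("adjacency obeys the power law on exact correlations", {
  pair <- make_cor_pair(0.5, n = 30, seed = 2)
  m <- rbind(g1 = pair$x, g2 = pair$y)
  colnames(m) <- sprintf("s%d", 1:30)
  a <- adjacency_matrix(m, beta = 6)
  expect_equal(a["g1", "g2"], 0.5^6, tolerance = 1e-12)  # 0.015625
  expect_equal(a, t(a))
  expect_equal(diag(a), c(g1 = 1, g2 = 1))

  perfect <- rbind(g1 = 1:10, g2 = 2 * (1:10) + 3)
  colnames(perfect) <- sprintf("s%d", 1:10)
  expect_equal(adjacency_matrix(perfect, 6)["g1", "g2"], 1)

  const <- rbind(g1 = rep(1, 10), g2 = 1:10)
  colnames(const) <- sprintf("s%d", 1:10)
  expect_error(adjacency_matrix(const, 2), "zero-variance")
})

test_that("TOM reproduces the hand-computed 3-gene example", {
  A <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, 3, byrow = TRUE)
  tom <- tom_similarity(A)
  expect_equal(tom[1, 2], (0.4 * 0.2 + 0.8) / (min(1.2, 1.0) + 1 - 0.8))
  expect_equal(tom[1, 2], 0.88 / 1.2)

  eye <- diag(4)
  expect_equal(tom_similarity(eye), eye)  # no shared neighbours

  bad <- A; bad[1, 2] <- 0.5
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("TOM equals the brute-force triple loop on random adjacencies", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    expect_lt(max(abs(tom_similarity(A) - tom_brute_force(A))), 1e-12)
  }
})

test_that("the soft-threshold scan behaves on structured and noise data", {
  blocks <- make_block_matrix(n_blocks = 3, block_size = 40, n_noise = 80,
                              n_samples = 60, loading = 2, seed = 5)
  sel <- pick_soft_threshold(blocks$matrix)
  expect_true(sel$beta >= 1 && sel$beta <= 20)
  expect_true(all(diff(sel$scan$mean_k) < 0))  # k-bar decreasing in beta

  noise <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:30)))
  low_power_fit <- pick_soft_threshold(noise)$scan$signed_r2[1]
  expect_lt(low_power_fit, 0.85)

  expect_error(pick_soft_threshold(noise[1:10, ]), ">= 30")
})

test_that("planted blocks are recovered as exactly labelled modules", {
  blocks <- make_block_matrix(n_blocks = 2, block_size = 80, n_noise = 0,
                              n_samples = 100, loading = 3, seed = 7)
  # within-block correlation 9/10 = 0.9, across ~ 0
  tom <- tom_similarity(adjacency_matrix(blocks$matrix, 6))
  part <- cluster_modules(tom, min_module_size = 60)
  expect_setequal(unique(part), c("turquoise", "blue"))
  expect_equal(as.integer(sort(table(part))), c(80L, 80L))
  # labels track size order when blocks differ
  small <- make_block_matrix(n_blocks = 1, block_size = 70, n_noise = 0,
                             n_samples = 100, loading = 3, seed = 8)
  big <- make_block_matrix(n_blocks = 1, block_size = 90, n_noise = 0,
                           n_samples = 100, loading = 3, seed = 9)
  rownames(small$matrix) <- sprintf("S%04d", 1:70)
  rownames(big$matrix) <- sprintf("B%04d", 1:90)
  m <- rbind(small$matrix, big$matrix)
  tom2 <- tom_similarity(adjacency_matrix(m, 6))
  part2 <- cluster_modules(tom2, min_module_size = 60)
  expect_equal(unname(part2[rownames(big$matrix)]),
               rep("turquoise", 90))  # largest module gets first color
  expect_equal(unname(part2[rownames(small$matrix)]), rep("blue", 70))
})

test_that("pure noise yields no modules and small inputs warn", {
  set.seed(11)
  noise <- matrix(rnorm(150 * 80), 150, 80,
                  dimnames = list(sprintf("g%d", 1:150), sprintf("s%d", 1:80)))
  tom <- tom_similarity(adjacency_matrix(noise, 6))
  expect_true(all(cluster_modules(tom, 60) == "grey"))
  expect_warning(part <- cluster_modules(tom[1:10, 1:10], 60), "min_module_size")
  expect_true(all(part == "grey"))
})

test_that("module recovery reaches adjusted Rand >= 0.9 across seeds", {
  aris <- vapply(1:10, function(s) {
    n_blocks <- sample(2:4, 1)
    blocks <- make_block_matrix(n_blocks = n_blocks, block_size = 60,
                                n_noise = 60, n_samples = 80,
                                loading = sqrt(7 / 3), seed = s)
    tom <- tom_similarity(adjacency_matrix(blocks$matrix, 6))
    part <- cluster_modules(tom, min_module_size = 60)
    adjusted_rand(part, blocks$truth)
  }, 1)
  expect_true(all(aris >= 0.9))
})

test_that("gene order permutation permutes but does not change the partition", {
  blocks <- make_block_matrix(n_blocks = 2, block_size = 70, n_noise = 30,
                              n_samples = 80, loading = 2, seed = 13)
  tom <- tom_similarity(adjacency_matrix(blocks$matrix, 6))
  part <- cluster_modules(tom, 60)
  set.seed(14)
  perm <- sample(nrow(blocks$matrix))
  tom_p <- tom_similarity(adjacency_matrix(blocks$matrix[perm, ], 6))
  part_p <- cluster_modules(tom_p, 60)
  expect_equal(adjusted_rand(part, part_p[names(part)]), 1)
})

test_that("eigengenes summarize modules with the right orientation", {
  blocks <- make_block_matrix(n_blocks = 1, block_size = 60, n_samples = 50,
                              loading = 3, seed = 15)
  me <- module_eigengene(blocks$matrix, rownames(blocks$matrix))
  expect_equal(sum(me^2), 1)
  cors <- cor(t(blocks$matrix), me)
  expect_gt(mean(cors), 0.8)  # tight module: high membership throughout

  # explained variance of the first component on a 0.9-correlation block
  xs <- t(scale(t(blocks$matrix)))
  sv <- svd(xs)
  expect_gt(sv$d[1]^2 / sum(sv$d^2), 0.8)

  # affine rescaling of member genes leaves the eigengene unchanged (sign aside)
  resc <- blocks$matrix * runif(60, 0.5, 3) + rnorm(60)
  me2 <- module_eigengene(resc, rownames(resc))
  expect_equal(abs(cor(me, me2)), 1, tolerance = 1e-10)

  single <- module_eigengene(blocks$matrix, rownames(blocks$matrix)[1])
  expect_equal(sum(single^2), 1)
  expect_error(module_eigengene(blocks$matrix, character(0)), "empty")
})

test_that("module-trait correlation and key-module selection follow the rules", {
  set.seed(17)
  trait <- rep(c(0, 1), each = 25)
  me_hit <- (trait - mean(trait)); me_hit <- me_hit / sqrt(sum(me_hit^2))
  me_null <- rnorm(50); me_null <- me_null / sqrt(sum(me_null^2))
  mt <- module_trait_correlation(
    list(turquoise = me_hit, blue = me_null), trait)
  expect_equal(mt$r[mt$module == "turquoise"], 1, tolerance = 1e-12)
  expect_lt(mt$p[mt$module == "turquoise"], 1e-20)

  flipped <- module_trait_correlation(list(turquoise = me_hit), 1 - trait)
  expect_equal(flipped$r, -1, tolerance = 1e-12)

  mt$size <- c(100, 80)
  expect_equal(select_key_module(mt), "turquoise")
  tie <- data.frame(module = c("blue", "turquoise"), r = c(0.4, -0.4),
                    p = c(0.01, 0.01), size = c(70, 90))
  expect_equal(select_key_module(tie), "turquoise")  # |r| tie -> larger module
  grey_only <- data.frame(module = "grey", r = 0.9, p = 0.01, size = 500)
  expect_error(select_key_module(grey_only), "non-grey")
  expect_error(module_trait_correlation(list(a = me_hit), rep(1, 50)),
               "constant")
})

test_that("gene significance and membership are bounded and informative", {
  blocks <- make_block_matrix(n_blocks = 1, block_size = 60, n_noise = 20,
                              n_samples = 60, loading = 3, seed = 19)
  trait <- rep(c(0, 1), each = 30)
  m <- blocks$matrix
  m["G0001", ] <- trait + rnorm(60, sd = 1e-6)  # gene tracking the trait
  tom <- tom_similarity(adjacency_matrix(m, 6))
  part <- cluster_modules(tom, 50)
  mods <- setdiff(unique(part), "grey")
  egs <- lapply(setNames(mods, mods), function(mm) {
    module_eigengene(m, names(part)[part == mm])
  })
  gsmm <- gene_significance_membership(m, trait, part, egs)
  expect_true(all(gsmm$GS >= 0 & gsmm$GS <= 1))
  expect_equal(gsmm$GS[gsmm$gene == "G0001"], 1, tolerance = 1e-6)
  tight <- gsmm[gsmm$module != "grey" & gsmm$gene != "G0001", ]
  expect_gt(median(tight$MM), 0.8)
  expect_true(all(is.na(gsmm$MM[gsmm$module == "grey"])))
})
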