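# Shared fixtures and small independent oracles used across test files.

# Separable two-Gaussian multi-cohort classification data: the first
# n_informative features shift by delta between classes.
make_sep_cohort <- function(n, p = 28, delta = 1.2, n_informative = 8,
                            seed = 1) {
  set.seed(seed)
  n_informative <- min(n_informative, p)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("hub%02d", 1:p)))
  X[, seq_len(n_informative)] <-
    X[, seq_len(n_informative)] + outer(y, rep(delta, n_informative))
  list(X = X, y = y)
}

# Block-correlated expression: n_blocks latent-factor modules of
# block_size genes each plus n_noise independent genes; within-block
# correlation loading^2 / (loading^2 + 1).
make_block_matrix <- function(n_blocks = 2, block_size = 80, n_noise = 0,
                              n_samples = 100, loading = 3, seed = 1) {
  set.seed(seed)
  n_genes <- n_blocks * block_size + n_noise
  truth <- c(rep(seq_len(n_blocks), each = block_size), rep(0L, n_noise))
  f <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  in_block <- truth > 0
  x[in_block, ] <- loading * f[truth[in_block], ] + x[in_block, , drop = FALSE]
  dimnames(x) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  list(matrix = x, truth = setNames(truth, rownames(x)))
}

# Adjusted Rand index from the contingency table (closed form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force O(n^3) topological overlap straight from the definition.
tom_brute_force <- function(A) {
  n <- nrow(A)
  tom <- diag(n)
  k <- rowSums(A) - diag(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  tom
}

# Pair-counting AUC (concordant + half ties over all pos/neg pairs).
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Two vectors with an exact Pearson correlation r (unit norm construction).
make_cor_pair <- function(r, n = 20, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  z <- residuals(lm(z ~ x))
  z <- (z - mean(z)) / sd(z)
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# Tiny restricted manifest for fast benchmark runs.
tiny_manifest <- function() {
  list(
    selectors = list(list(algorithm = "Lasso")),
    modelers = list(list(algorithm = "LDA")),
    standalones = list(list(algorithm = "Ridge"))
  )
}
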