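# Size-ordered standard module color sequence; "grey" is reserved for
# unassigned genes.
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Keep genes whose variability exceeds a threshold
#'
#' @param matrix genes x samples matrix (>= 2 samples).
#' @param sd_min minimum sample standard deviation (strict `>`).
#' @return the filtered matrix.
#' @export
filter_variable_genes <- function(matrix, sd_min = 0.5) {
  if (ncol(matrix) < 2) stop("need >= 2 samples to compute standard deviations")
  sds <- sqrt(rowSums((matrix - rowMeans(matrix))^2) / (ncol(matrix) - 1))
  matrix[sds > sd_min, , drop = FALSE]
}

#' Soft-thresholding power adjacency
#'
#' Unsigned weighted network: \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with
#' unit diagonal.
#'
#' @param matrix genes x samples matrix; no zero-variance genes.
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric gene x gene adjacency with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(matrix, beta) {
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(matrix, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(head(rownames(matrix)[sds == 0], 5), collapse = ", "))
  }
  a <- abs(cor(t(matrix)))^beta
  diag(a) <- 1
  a
}

#' Scan candidate soft-thresholding powers for scale-free fit
#'
#' For each power the unsigned adjacency and connectivities
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} are computed; the scale-free fit
#' index is the \eqn{R^2} of the log10 frequency versus log10 mean
#' connectivity regression over at most 10 connectivity bins, signed by
#' the negated slope sign (so scale-free-like decreasing distributions
#' score positively). The chosen power is the smallest one reaching
#' `r2_target`, otherwise the maximizer of the signed index.
#'
#' @param matrix genes x samples matrix (>= 30 genes).
#' @param powers candidate integer powers.
#' @param r2_target signed fit index target (default 0.85).
#' @return list with `beta` and `scan` (data.frame `power`,
#'   `signed_r2`, `mean_k`).
#' @export
pick_soft_threshold <- function(matrix, powers = 1:20, r2_target = 0.85) {
  if (nrow(matrix) < 30) stop("soft-threshold scan needs >= 30 genes")
  cors <- abs(cor(t(matrix)))
  if (anyNA(cors) || all(cors == 1)) {
    stop("degenerate expression: constant or perfectly collinear genes")
  }
  diag(cors) <- 0
  scan <- data.frame(power = powers, signed_r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(cors^powers[i])
    scan$mean_k[i] <- mean(k)
    scan$signed_r2[i] <- scale_free_fit(k)
  }
  hit <- which(scan$signed_r2 >= r2_target)
  beta <- if (length(hit)) powers[hit[1]] else powers[which.max(scan$signed_r2)]
  list(beta = beta, scan = scan)
}

# Signed scale-free topology fit index of a connectivity vector:
# -sign(slope) * R^2 of log10 p(k) on log10 mean-k over <= 10
# equal-width connectivity bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  p_k <- tapply(k, bins, length) / length(k)
  k_bar <- tapply(k, bins, mean)
  keep <- !is.na(p_k) & p_k > 0 & k_bar > 0
  if (sum(keep) < 3) return(0)
  x <- log10(k_bar[keep]); y <- log10(p_k[keep])
  if (sd(x) == 0 || sd(y) == 0) return(0)
  r <- cor(x, y)
  -sign(r) * r^2   # slope sign equals correlation sign
}

#' Topological overlap from an adjacency matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad TOM_{ii} = 1}
#'
#' @param A symmetric adjacency, unit diagonal, entries in `[0, 1]`.
#' @return symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-12)) stop("adjacency must be symmetric")
  a <- A
  diag(a) <- 0
  L <- a %*% a             # includes no i/j self terms since diag 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Agglomerates on `1 - TOM` with average linkage and applies a static
#' cut at `cut_frac` times the maximum merge height (a documented
#' simplification of dynamic tree cutting). Clusters smaller than
#' `min_module_size` are assigned `"grey"`; remaining modules are
#' labelled by the size-ordered standard color sequence (largest =
#' `"turquoise"`).
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size minimum genes per module (default 60).
#' @param cut_frac static cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @return named character vector gene -> module color.
#' @export
cluster_modules <- function(tom, min_module_size = 60, cut_frac = 0.99) {
  genes <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(setNames(rep("grey", nrow(tom)), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- setNames(rep("grey", length(cl)), genes)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) {
      labels[cl == as.integer(ord[i])] <- module_colors[i]
    }
  }
  labels
}

#' Module eigengene
#'
#' First right singular vector (sample scores) of the gene-standardized
#' module submatrix, unit norm, sign-oriented so the mean correlation
#' with the module's genes is positive.
#'
#' @param matrix genes x samples matrix.
#' @param module_genes character vector of module member genes.
#' @return unit-norm numeric vector over samples.
#' @export
module_eigengene <- function(matrix, module_genes) {
  if (!length(module_genes)) stop("module is empty")
  x <- matrix[module_genes, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  if (nrow(x) == 1) {
    v <- as.vector(x) / sqrt(sum(x^2))
  } else {
    v <- svd(x, nu = 0, nv = 1)$v[, 1]
  }
  cors <- as.vector(cor(t(x), v))
  if (mean(cors) < 0) v <- -v
  setNames(v, colnames(matrix))
}

#' Module-trait correlations
#'
#' @param eigengenes named list of module eigengene vectors.
#' @param trait numeric 0/1 (Control = 0, Treat = 1), both classes present.
#' @return data.frame `module`, `r`, `p` (two-sided t-test on
#'   `n - 2` degrees of freedom).
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (length(unique(trait)) < 2) stop("trait is constant")
  n <- length(trait)
  rows <- lapply(names(eigengenes), function(m) {
    r <- cor(eigengenes[[m]], trait)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(module = m, r = r, p = 2 * pt(-abs(t_stat), df = n - 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the key module by strongest trait correlation
#'
#' @param summary data.frame from [module_trait_correlation()], plus a
#'   `size` column used to break ties (larger wins). `"grey"` is never
#'   selected.
#' @return the selected module label.
#' @export
select_key_module <- function(summary) {
  s <- summary[summary$module != "grey", , drop = FALSE]
  if (!nrow(s)) stop("no non-grey modules to select from")
  size <- s$size %||% rep(0, nrow(s))
  if (is.null(s$size)) s$size <- size
  o <- order(-abs(s$r), -s$size, s$module)
  s$module[o[1]]
}

#' Gene significance and module membership
#'
#' `GS` is the absolute gene-trait correlation; `MM` the correlation of a
#' gene with its own module's eigengene (`NA` for grey genes).
#'
#' @param matrix genes x samples matrix.
#' @param trait numeric 0/1 trait.
#' @param partition named gene -> module vector from [cluster_modules()].
#' @param eigengenes named list of module eigengenes.
#' @return data.frame `gene`, `module`, `GS`, `MM`.
#' @export
gene_significance_membership <- function(matrix, trait, partition, eigengenes) {
  genes <- rownames(matrix)
  gs <- abs(as.vector(cor(t(matrix), trait)))
  mm <- rep(NA_real_, length(genes))
  for (m in names(eigengenes)) {
    idx <- which(partition[genes] == m)
    if (length(idx)) {
      mm[idx] <- as.vector(cor(t(matrix[idx, , drop = FALSE]), eigengenes[[m]]))
    }
  }
  data.frame(gene = genes, module = unname(partition[genes]),
             GS = gs, MM = mm, stringsAsFactors = FALSE)
}

#' Run the full co-expression stage
#'
#' Variance filter, soft-threshold scan, adjacency, TOM, module
#' detection, eigengenes, module-trait correlation and key-module
#' selection in one call.
#'
#' @param matrix genes x samples matrix.
#' @param trait numeric 0/1 trait per sample.
#' @param sd_min variance-filter threshold.
#' @param min_module_size minimum module size.
#' @param powers candidate soft powers.
#' @param r2_target scale-free fit target.
#' @return list with `beta`, `scan`, `partition`, `eigengenes`,
#'   `module_trait` (with sizes), `key_module`, `gs_mm`,
#'   `module_genes` (members of the key module).
#' @export
run_coexpr <- function(matrix, trait, sd_min = 0.5, min_module_size = 60,
                       powers = 1:20, r2_target = 0.85) {
  filtered <- filter_variable_genes(matrix, sd_min)
  sel <- pick_soft_threshold(filtered, powers, r2_target)
  # A high scale-free-optimal power can dilute topological overlap below
  # what the static cut resolves; step the power down until modules
  # emerge (the adaptivity dynamic tree cutting would otherwise provide).
  beta <- sel$beta
  repeat {
    tom <- tom_similarity(adjacency_matrix(filtered, beta))
    partition <- cluster_modules(tom, min_module_size)
    mods <- setdiff(unique(partition), "grey")
    if (length(mods) || beta <= 2) break
    beta <- beta - 2
  }
  if (beta != sel$beta) {
    message(sprintf("soft power lowered from %d to %d to resolve modules",
                    sel$beta, beta))
    sel$beta <- beta
  }
  if (!length(mods)) {
    stop("no co-expression modules detected at any scanned soft power")
  }
  eigengenes <- lapply(setNames(mods, mods), function(m) {
    module_eigengene(filtered, names(partition)[partition == m])
  })
  mt <- module_trait_correlation(eigengenes, trait)
  mt$size <- as.integer(table(partition)[mt$module])
  key <- select_key_module(mt)
  list(beta = sel$beta, scan = sel$scan, partition = partition,
       eigengenes = eigengenes, module_trait = mt, key_module = key,
       gs_mm = gene_significance_membership(filtered, trait, partition, eigengenes),
       module_genes = sort(names(partition)[partition == key]))
}
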