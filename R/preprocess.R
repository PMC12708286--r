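#' Collapse a probe-level matrix to gene level
#'
#' Probes flagged `unmapped` or `ambiguous` in the annotation are dropped;
#' for each gene the per-sample arithmetic mean over its remaining probes
#' is taken (the classical "average replicate probes" collapse). Genes are
#' returned in lexicographic order. The median is available as an
#' alternative summary.
#'
#' @param probe_matrix probes x samples numeric matrix with probe rownames.
#' @param annotation data.frame with columns `probe_id`, `gene_symbol`,
#'   `status` (`mapped`/`unmapped`/`ambiguous`); each probe appears once.
#' @param summary `"mean"` (default) or `"median"`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(probe_matrix, annotation, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  missing_probes <- setdiff(rownames(probe_matrix), annotation$probe_id)
  if (length(missing_probes)) {
    stop("probes absent from annotation: ",
         paste(head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) ", ...")
  }
  ann <- annotation[match(rownames(probe_matrix), annotation$probe_id), ]
  keep <- ann$status == "mapped"
  m <- probe_matrix[keep, , drop = FALSE]
  gene <- ann$gene_symbol[keep]
  fun <- if (summary == "mean") colMeans else function(x) apply(x, 2, median)
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in split(seq_along(gene), gene)) {
    out[gene[g[1]], ] <- fun(m[g, , drop = FALSE])
  }
  out
}

#' Impute missing entries by k-nearest-neighbour weighted averaging
#'
#' For a gene with a missing value in sample `j`, the `k` genes observed at
#' `j` that are nearest in Euclidean distance over mutually observed
#' samples are found, and the missing value is replaced by their
#' 1/distance-weighted mean at `j`. A zero-distance neighbour contributes
#' its value exactly. Observed entries are never altered.
#'
#' Distances over partially observed pairs are rescaled to the full sample
#' count (the usual "mean over shared coordinates" convention).
#'
#' @param matrix genes x samples matrix with `NA` for missing entries.
#' @param k number of neighbours (default 10).
#' @return the matrix with all entries finite.
#' @export
knn_impute <- function(matrix, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (!anyNA(matrix)) return(matrix)
  all_missing <- rowSums(!is.na(matrix)) == 0
  if (any(all_missing)) {
    stop("gene(s) with all values missing: ",
         paste(head(rownames(matrix)[all_missing], 5), collapse = ", "))
  }
  incomplete <- which(rowSums(is.na(matrix)) > 0)
  out <- matrix
  for (i in incomplete) {
    xi <- matrix[i, ]
    obs_i <- !is.na(xi)
    diffs <- sweep(matrix[, obs_i, drop = FALSE], 2, xi[obs_i])
    shared <- rowSums(!is.na(diffs))
    d2 <- rowMeans(diffs^2, na.rm = TRUE)  # mean over shared coordinates
    d <- sqrt(d2)
    d[i] <- Inf
    d[shared == 0] <- Inf
    for (j in which(!obs_i)) {
      cand <- which(!is.na(matrix[, j]))
      cand <- cand[cand != i & is.finite(d[cand])]
      if (!length(cand)) {
        stop(sprintf("no complete neighbours for gene '%s' at sample '%s'",
                     rownames(matrix)[i], colnames(matrix)[j]))
      }
      nb <- cand[order(d[cand])[seq_len(min(k, length(cand)))]]
      dn <- d[nb]
      if (any(dn == 0)) {
        out[i, j] <- mean(matrix[nb[dn == 0], j])
      } else {
        w <- 1 / dn
        out[i, j] <- sum(w * matrix[nb, j]) / sum(w)
      }
    }
  }
  out
}

#' Decide and apply the automatic log2 transformation
#'
#' Raw-intensity microarray matrices are detected by a quantile rule over
#' all entries pooled: if the 99th percentile exceeds 100, or the
#' max-minus-min range exceeds 50 while the 25th percentile is positive,
#' the matrix is replaced by `log2(x + 1)`. Already-log data pass through
#' unchanged, making the rule idempotent on its own output.
#'
#' @param matrix numeric matrix, all entries finite.
#' @return list with `matrix` and logical `applied`.
#' @export
auto_log2 <- function(matrix) {
  v <- as.vector(matrix)
  if (anyNA(v)) stop("auto_log2 requires a complete matrix; impute first")
  q <- quantile(v, c(0.25, 0.99), names = FALSE)
  rng <- max(v) - min(v)
  trigger <- q[2] > 100 || (rng > 50 && q[1] > 0)
  if (!trigger) return(list(matrix = matrix, applied = FALSE))
  if (min(v) <= -1) {
    stop("log2 transform triggered but matrix has values <= -1")
  }
  list(matrix = log2(matrix + 1), applied = TRUE)
}

#' Quantile-normalize the columns of an expression matrix
#'
#' Every sample is forced onto the common distribution of across-sample
#' mean order statistics. Ties within a column receive the mean of the
#' reference values at their tied ranks, so the transform is idempotent.
#'
#' @param matrix genes x samples matrix, no missing values.
#' @return normalized matrix with identical column distributions.
#' @export
quantile_normalize <- function(matrix) {
  if (anyNA(matrix)) stop("quantile_normalize requires a complete matrix; impute first")
  sorted <- apply(matrix, 2, sort)
  reference <- rowMeans(sorted)
  out <- apply(matrix, 2, function(x) {
    res <- numeric(length(x))
    res[order(x)] <- reference
    ave(res, x, FUN = mean)  # ties share the mean reference value
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Merge preprocessed cohorts on their common genes
#'
#' @param matrices named list of genes x samples matrices (>= 2).
#' @return list with `matrix` (rows = sorted gene intersection, columns
#'   concatenated) and `cohort_of` (named character vector sample -> cohort).
#' @export
merge_cohorts <- function(matrices) {
  if (length(matrices) < 2) stop("merge_cohorts needs at least two cohorts")
  if (is.null(names(matrices))) names(matrices) <- sprintf("cohort%d", seq_along(matrices))
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(genes)) stop("cohorts share no genes; cannot merge")
  genes <- sort(genes)
  all_samples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample ids across cohorts: ",
         paste(head(unique(all_samples[duplicated(all_samples)]), 5), collapse = ", "))
  }
  merged <- do.call(cbind, lapply(matrices, function(m) m[genes, , drop = FALSE]))
  colnames(merged) <- all_samples
  cohort_of <- rep(names(matrices), vapply(matrices, ncol, 1L))
  names(cohort_of) <- all_samples
  list(matrix = merged, cohort_of = cohort_of)
}

#' Principal-component scores of samples
#'
#' SVD of the gene-centred matrix; components are ordered by decreasing
#' variance and sign-oriented so each component's largest-magnitude gene
#' loading is positive.
#'
#' @param matrix genes x samples matrix.
#' @param n_components number of components (<= number of samples).
#' @return list with `scores` (samples x components) and
#'   `explained` (variance fractions).
#' @export
pca_scores <- function(matrix, n_components = 2) {
  if (ncol(matrix) < n_components) {
    stop("fewer samples than requested components")
  }
  x <- matrix - rowMeans(matrix)
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(i) {
    u <- sv$u[, i]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, 1)
  scores <- sweep(sv$v, 2, sv$d[seq_len(n_components)] * flip, `*`)
  rownames(scores) <- colnames(matrix)
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  list(scores = scores,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}
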