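#' Write an expression matrix as TSV
#'
#' First column `gene`, remaining columns are sample ids.
#'
#' @param matrix genes x samples matrix.
#' @param path output file.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with first column `gene` and one column per sample.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a phenotype table
#'
#' @param path TSV with columns `sample_id`, `cohort`, `group`.
#' @return data.frame with the three columns; `group` validated to
#'   `Control`/`Treat`.
#' @export
read_pheno_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "cohort", "group")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), c("Control", "Treat"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df[needed]
}
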