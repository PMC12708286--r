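#' Read a gene list from TSV or GMT
#'
#' TSV: one symbol per line in the first column; a `symbol`/`gene` header
#' is skipped. GMT: every row is `name<TAB>description<TAB>gene...`; one
#' set per row. Symbols are whitespace-trimmed, case preserved,
#' deduplicated keeping the first occurrence.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return for TSV a character vector of symbols; for GMT a named list of
#'   such vectors.
#' @export
read_gene_list <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene list file: ", path)
  if (format == "tsv") {
    sym <- trimws(vapply(strsplit(lines, "\t"), `[`, "", 1))
    if (tolower(sym[1]) %in% c("symbol", "gene", "gene_symbol")) sym <- sym[-1]
    sym <- sym[nzchar(sym)]
    if (!length(sym)) stop("empty gene list file: ", path)
    return(unique(sym))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t")[[1]])
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT row at line %d: fewer than 3 fields", i))
    }
    genes <- unique(fields[-(1:2)])
    sets[[fields[1]]] <- genes[nzchar(genes)]
  }
  sets
}

#' Intersect DEGs, key-module genes and a mitochondrial gene list
#'
#' The hub candidate set is the sorted three-way intersection; the seven
#' regions of the three-set Venn diagram are reported alongside.
#'
#' @param degs,module_genes,mito character vectors of gene symbols.
#' @return list with `hub` (sorted symbols) and `venn` (named counts of
#'   the 7 exclusive regions: `deg_only`, `module_only`, `mito_only`,
#'   `deg_module`, `deg_mito`, `module_mito`, `all_three`).
#' @export
intersect_hub <- function(degs, module_genes, mito) {
  degs <- unique(trimws(degs)); module_genes <- unique(trimws(module_genes))
  mito <- unique(trimws(mito))
  u <- union(union(degs, module_genes), mito)
  in_d <- u %in% degs; in_m <- u %in% module_genes; in_t <- u %in% mito
  venn <- c(
    deg_only = sum(in_d & !in_m & !in_t),
    module_only = sum(!in_d & in_m & !in_t),
    mito_only = sum(!in_d & !in_m & in_t),
    deg_module = sum(in_d & in_m & !in_t),
    deg_mito = sum(in_d & !in_m & in_t),
    module_mito = sum(!in_d & in_m & in_t),
    all_three = sum(in_d & in_m & in_t)
  )
  hub <- sort(u[in_d & in_m & in_t])
  if (!length(hub)) warning("empty hub set: the three gene sets share no genes")
  list(hub = hub, venn = venn)
}
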