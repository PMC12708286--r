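#' Configuration for the multi-cohort expression simulator
#'
#' Builds and validates the parameter set for [simulate_cohorts()]. The
#' generator emulates several independent case/control microarray cohorts:
#' gene baselines on the log2 scale, latent-factor co-expression modules,
#' a planted set of differentially expressed (DE) genes, cohort-specific
#' additive and multiplicative batch effects, a labelled "mitochondrial"
#' gene subset enriched for DE genes, and missing-at-random entries.
#'
#' The signal model for gene g, sample j in cohort b is
#' \deqn{x_{gj} = \mu_g + l_g f_{m(g),j} + \delta\,[j \in Treat][g \in DE]
#'   + \gamma_{bg} + \psi_b \epsilon_{gj}}
#' with baseline \eqn{\mu_g \sim U(4, 12)} log2 units, per-sample module
#' factors \eqn{f \sim N(0,1)}, loading \eqn{l_g =} `module_loading` for
#' module members and 0 otherwise, batch shifts
#' \eqn{\gamma_{bg} \sim N(0, batch\_shift\_sd^2)}, a cohort-wide noise
#' scale \eqn{\psi_b \sim U(batch\_scale\_range)} and
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}.
#'
#' @param n_cohorts number of independent cohorts.
#' @param n_control,n_treat samples per group per cohort.
#' @param n_genes number of genes.
#' @param module_sizes integer vector of planted module sizes (genes are
#'   assigned to modules in blocks; the first module is the largest).
#' @param n_de_genes number of planted DE genes.
#' @param delta Treat-minus-Control effect size in log2 units.
#' @param batch_shift_sd sd of per-cohort additive gene-level shifts (log2).
#' @param batch_scale_range length-2 interval for the cohort-wide
#'   multiplicative noise scale.
#' @param noise_sd residual sd in log2 units.
#' @param mito_fraction proportion of genes labelled mitochondrial.
#' @param mito_de_enrichment relative sampling weight of DE genes when the
#'   mitochondrial subset is drawn (>1 over-represents DE genes).
#' @param de_module_fraction proportion of DE genes planted inside the
#'   first (largest) module, so the DEG/module/mito funnel is non-empty
#'   by construction.
#' @param module_loading factor loading of module member genes. The
#'   default realizes a within-module pairwise correlation of 0.7
#'   (`l^2 / (l^2 + noise_sd^2) = 0.7`), the calibration the module
#'   recovery properties assume.
#' @param missing_rate proportion of entries set missing, in `[0, 1)`.
#' @param raw_scale emit `2^x` raw-style intensities instead of log2.
#' @param probes_per_gene probes per gene for [expand_to_probes()].
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @return a validated `mitodx_sim_config` list.
#' @seealso [simulate_cohorts()]
#' @export
sim_config <- function(n_cohorts = 3, n_control = 20, n_treat = 20,
                       n_genes = 2000, module_sizes = c(150, 100, 80),
                       n_de_genes = 120, delta = 2,
                       batch_shift_sd = 0.3, batch_scale_range = c(0.8, 1.25),
                       noise_sd = 1, mito_fraction = 0.15,
                       mito_de_enrichment = 4, de_module_fraction = 0.7,
                       module_loading = sqrt(7 / 3) * noise_sd,
                       missing_rate = 0, raw_scale = FALSE,
                       probes_per_gene = 1, seed = 1) {
  cfg <- list(
    n_cohorts = n_cohorts, n_control = n_control, n_treat = n_treat,
    n_genes = n_genes, module_sizes = as.integer(module_sizes),
    n_de_genes = n_de_genes, delta = delta,
    batch_shift_sd = batch_shift_sd, batch_scale_range = batch_scale_range,
    noise_sd = noise_sd, mito_fraction = mito_fraction,
    mito_de_enrichment = mito_de_enrichment,
    de_module_fraction = de_module_fraction,
    module_loading = module_loading,
    missing_rate = missing_rate, raw_scale = raw_scale,
    probes_per_gene = as.integer(probes_per_gene), seed = as.integer(seed)
  )
  for (f in c("n_cohorts", "n_control", "n_treat", "n_genes", "probes_per_gene")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop_config(f, "must be a positive integer")
    }
  }
  if (any(cfg$module_sizes < 1)) stop_config("module_sizes", "all counts positive")
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop_config("module_sizes", "sum(module_sizes) must not exceed n_genes")
  }
  if (cfg$n_de_genes > cfg$n_genes) stop_config("n_de_genes", "exceeds n_genes")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_config("missing_rate", "must lie in [0, 1)")
  }
  if (cfg$mito_fraction < 0 || cfg$mito_fraction > 1) {
    stop_config("mito_fraction", "must lie in [0, 1]")
  }
  if (length(cfg$batch_scale_range) != 2L ||
      any(cfg$batch_scale_range <= 0) ||
      diff(cfg$batch_scale_range) < 0) {
    stop_config("batch_scale_range", "must be a positive non-decreasing interval")
  }
  if (cfg$noise_sd <= 0) stop_config("noise_sd", "must be positive")
  if (cfg$de_module_fraction < 0 || cfg$de_module_fraction > 1) {
    stop_config("de_module_fraction", "must lie in [0, 1]")
  }
  class(cfg) <- "mitodx_sim_config"
  cfg
}

#' Simulate multi-cohort case/control expression data with known truth
#'
#' @param cfg a [sim_config()] object.
#' @return a list with components:
#'   \describe{
#'     \item{matrices}{named list of per-cohort genes x samples matrices
#'       (log2 scale unless `raw_scale`), possibly with `NA` entries.}
#'     \item{pheno}{data.frame with `sample_id`, `cohort`, `group`
#'       (`Control`/`Treat`).}
#'     \item{truth}{list: `de_genes`, `module_assignment` (0 = none),
#'       `mito_genes`, `batch` (per-cohort `shift` vector and `scale`).}
#'   }
#' @export
simulate_cohorts <- function(cfg) {
  if (!inherits(cfg, "mitodx_sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  module_assignment <- integer(cfg$n_genes)
  pos <- 1L
  for (m in seq_along(cfg$module_sizes)) {
    module_assignment[pos:(pos + cfg$module_sizes[m] - 1L)] <- m
    pos <- pos + cfg$module_sizes[m]
  }
  names(module_assignment) <- genes

  # Plant DE genes: a fixed fraction inside the first module, the rest
  # among module-free background genes (falling back to any non-module-1
  # gene when the background is too small).
  n_de_mod <- min(round(cfg$de_module_fraction * cfg$n_de_genes),
                  sum(module_assignment == 1L))
  de_idx <- integer(0)
  if (n_de_mod > 0) {
    de_idx <- sample(which(module_assignment == 1L), n_de_mod)
  }
  n_de_rest <- cfg$n_de_genes - n_de_mod
  if (n_de_rest > 0) {
    pool <- setdiff(which(module_assignment == 0L), de_idx)
    if (length(pool) < n_de_rest) {
      pool <- setdiff(which(module_assignment != 1L), de_idx)
    }
    de_idx <- c(de_idx, sample(pool, n_de_rest))
  }
  de_genes <- sort(genes[de_idx])
  is_de <- genes %in% de_genes

  # Mitochondrial label: weighted sample without replacement, DE genes
  # over-represented by mito_de_enrichment.
  n_mito <- round(cfg$mito_fraction * cfg$n_genes)
  w <- ifelse(is_de, cfg$mito_de_enrichment, 1)
  mito_genes <- sort(sample(genes, n_mito, prob = w))

  mu <- runif(cfg$n_genes, 4, 12)
  loading <- ifelse(module_assignment > 0L, cfg$module_loading, 0)
  n_per <- cfg$n_control + cfg$n_treat
  group <- rep(c("Control", "Treat"), c(cfg$n_control, cfg$n_treat))
  n_modules <- length(cfg$module_sizes)

  matrices <- list()
  pheno <- list()
  batch <- list()
  for (b in seq_len(cfg$n_cohorts)) {
    cohort <- sprintf("cohort%d", b)
    samples <- sprintf("%s_s%02d", cohort, seq_len(n_per))
    gamma <- rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
    psi <- runif(1, cfg$batch_scale_range[1], cfg$batch_scale_range[2])
    f <- matrix(rnorm(n_modules * n_per), n_modules, n_per)
    x <- mu + gamma +
      loading * (if (n_modules) f[pmax(module_assignment, 1L), , drop = FALSE] else 0) *
        (module_assignment > 0L) +
      outer(is_de * cfg$delta, as.numeric(group == "Treat")) +
      psi * matrix(rnorm(cfg$n_genes * n_per, 0, cfg$noise_sd), cfg$n_genes, n_per)
    dimnames(x) <- list(genes, samples)
    if (cfg$raw_scale) x <- 2^x
    if (cfg$missing_rate > 0) {
      x <- inject_missing(x, cfg$missing_rate,
                          seed = derive_seed(cfg$seed, paste0("missing_", cohort)))
    }
    matrices[[cohort]] <- x
    pheno[[cohort]] <- data.frame(sample_id = samples, cohort = cohort,
                                  group = group, stringsAsFactors = FALSE)
    batch[[cohort]] <- list(shift = gamma, scale = psi)
  }

  list(
    matrices = matrices,
    pheno = do.call(rbind, c(pheno, list(make.row.names = FALSE))),
    truth = list(de_genes = de_genes, module_assignment = module_assignment,
                 mito_genes = mito_genes, batch = batch)
  )
}

#' Expand a gene-level matrix to probe level
#'
#' Each gene is emitted as `probes_per_gene` probes (the gene value plus a
#' small fixed probe offset), together with a probe annotation table. A
#' configurable fraction of probes is flagged `unmapped` or `ambiguous`
#' to exercise the probe-collapse stage.
#'
#' @param matrix genes x samples matrix.
#' @param probes_per_gene probes emitted per gene (>= 1).
#' @param probe_offset_sd sd of the per-probe constant offset (0 makes the
#'   collapse an exact round trip).
#' @param frac_unmapped,frac_ambiguous fractions of probes flagged.
#' @param seed integer seed.
#' @return list with `probe_matrix` and `annotation` (data.frame
#'   `probe_id`, `gene_symbol`, `status`).
#' @export
expand_to_probes <- function(matrix, probes_per_gene = 2, probe_offset_sd = 0.1,
                             frac_unmapped = 0, frac_ambiguous = 0, seed = 1) {
  if (probes_per_gene < 1) stop_config("probes_per_gene", "must be >= 1")
  set.seed(seed)
  genes <- rownames(matrix)
  probe_ids <- as.vector(t(outer(genes, seq_len(probes_per_gene),
                                 function(g, k) sprintf("%s_at%d", g, k))))
  gene_of <- rep(genes, each = probes_per_gene)
  offsets <- rnorm(length(probe_ids), 0, probe_offset_sd)
  probe_matrix <- matrix[gene_of, , drop = FALSE] + offsets
  rownames(probe_matrix) <- probe_ids
  status <- rep("mapped", length(probe_ids))
  n_flag <- round(c(frac_unmapped, frac_ambiguous) * length(probe_ids))
  flagged <- sample(seq_along(probe_ids), sum(n_flag))
  if (n_flag[1] > 0) status[flagged[seq_len(n_flag[1])]] <- "unmapped"
  if (n_flag[2] > 0) status[flagged[n_flag[1] + seq_len(n_flag[2])]] <- "ambiguous"
  annotation <- data.frame(probe_id = probe_ids, gene_symbol = gene_of,
                           status = status, stringsAsFactors = FALSE)
  list(probe_matrix = probe_matrix, annotation = annotation)
}

#' Introduce missing-completely-at-random entries
#'
#' @param matrix numeric matrix.
#' @param rate probability each entry is set `NA`, in `[0, 1)`.
#' @param seed integer seed; the mask is reproducible given it.
#' @return the matrix with `NA` entries.
#' @export
inject_missing <- function(matrix, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop_config("missing_rate", "must lie in [0, 1)")
  if (rate == 0) return(matrix)
  set.seed(seed)
  mask <- runif(length(matrix)) < rate
  matrix[mask] <- NA_real_
  matrix
}
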