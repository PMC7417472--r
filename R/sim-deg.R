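#' Simulate gene models tiled along a chromosome
#'
#' Lays `n_genes` non-overlapping gene models at regular intervals along one
#' chromosome, for use as a synthetic annotation in candidate-gene tests.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length in bp.
#' @param gene_length_bp Length of each gene body (default 3 kb).
#' @param seed Integer seed (strand assignment).
#' @return A tibble: `gene_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`.
#' @export
simulate_gene_models <- function(n_genes, chrom = "chr1",
                                 chrom_length_bp = 30e6,
                                 gene_length_bp = 3000, seed = 1L) {
  if (n_genes == 0)
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character()))
  stopifnot(is_count(n_genes), gene_length_bp * n_genes <= chrom_length_bp)
  set.seed(stage_seed(seed, "genes"))
  spacing <- chrom_length_bp / n_genes
  start <- pmax(1, round(spacing * (seq_len(n_genes) - 0.5) - gene_length_bp / 2))
  tibble(
    gene_id = sprintf("%s_g%04d", chrom, seq_len(n_genes)),
    chrom = chrom,
    start = start,
    end = pmin(start + gene_length_bp - 1, chrom_length_bp),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

#' Simulate a differential-expression (DEG) table
#'
#' Builds a per-gene, per-contrast table of log2 expression ratios and FDR
#' values with planted truth: designated causal genes are significant
#' (FDR drawn uniformly on \[0, 0.01\], safely under the 0.05 cutoff) with
#' the stated log2-ratio in the designated contrasts, while all other
#' gene-by-contrast cells are null (FDR uniform on \[0, 1\], small ratios).
#'
#' @param gene_models Tibble from [simulate_gene_models()] or
#'   [read_gene_models()].
#' @param causal_genes Character vector of gene ids (subset of
#'   `gene_models$gene_id`) to make differentially expressed.
#' @param contrasts All contrast labels to emit (default the four
#'   within/between-variety contrasts `TWGvsTIR`, `WGvsIR`, `IRvsTIR`,
#'   `WGvsTWG`).
#' @param causal_contrasts Contrasts in which causal genes respond (default
#'   the within-variety salt-response contrasts `IRvsTIR`, `WGvsTWG`).
#' @param causal_log2fc Log2 ratio of causal genes in causal contrasts
#'   (default -2; a small Gaussian jitter is added).
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `contrast`, `log2_ratio`, `fdr`,
#'   `significant`, `direction`.
#' @export
simulate_deg_table <- function(gene_models,
                               causal_genes = character(),
                               contrasts = c("TWGvsTIR", "WGvsIR",
                                             "IRvsTIR", "WGvsTWG"),
                               causal_contrasts = c("IRvsTIR", "WGvsTWG"),
                               causal_log2fc = -2,
                               seed = 1L) {
  stopifnot(is.data.frame(gene_models))
  if (nrow(gene_models) == 0)
    return(tibble(gene_id = character(), contrast = character(),
                  log2_ratio = numeric(), fdr = numeric(),
                  significant = logical(), direction = character()))
  unknown <- setdiff(causal_genes, gene_models$gene_id)
  if (length(unknown) > 0)
    abort(paste0("unknown causal gene id(s): ", paste(unknown, collapse = ", ")))
  set.seed(stage_seed(seed, "deg"))

  out <- tidyr::expand_grid(gene_id = gene_models$gene_id, contrast = contrasts)
  n <- nrow(out)
  out$log2_ratio <- rnorm(n, 0, 0.3)
  out$fdr <- runif(n)
  causal <- out$gene_id %in% causal_genes & out$contrast %in% causal_contrasts
  out$log2_ratio[causal] <- causal_log2fc + rnorm(sum(causal), 0, 0.2)
  out$fdr[causal] <- runif(sum(causal), 0, 0.01)
  dplyr::bind_cols(out, classify_deg(out$log2_ratio, out$fdr))
}
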