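#' Configuration for the synthetic F2 bulked-segregant experiment
#'
#' Bundles every generative parameter of the simulated cross: population and
#' bulk sizes, marker map, the single additive QTL (position and fraction of
#' phenotypic variance explained), and the pooled-sequencing depth model.
#' Defaults emulate a large rice F2 design: 983 lines, extreme bulks of 40,
#' one additive QTL explaining 24.9% of the phenotypic variance, and pooled
#' sequencing at a mean depth of 27.6x.
#'
#' @param n_lines Number of F2 individuals (default 983).
#' @param bulk_size Number of lines in each extreme pool (default 40);
#'   `2 * bulk_size` must not exceed `n_lines`.
#' @param n_chrom Number of chromosomes (default 1).
#' @param chrom_length_bp Length of each chromosome in bp (default 30 Mb).
#' @param n_snps_per_chrom Markers per chromosome (default 5000), evenly
#'   spaced along the physical map.
#' @param qtl_chrom Chromosome carrying the QTL (default `"chr1"`).
#' @param qtl_pos_bp QTL position in bp; the marker nearest this position is
#'   treated as the causal locus (default mid-chromosome).
#' @param qtl_pve Fraction of phenotypic variance explained by the QTL, in
#'   `[0, 1)` (default 0.249).
#' @param mean_depth Mean sequencing depth per SNP per pool (default 27.6).
#' @param depth_model Depth distribution; currently `"poisson"` (Poisson with
#'   mean `mean_depth`, truncated at >= 1) or `"fixed"` (constant
#'   `round(mean_depth)`).
#' @param cm_per_mb Recombination rate used to convert physical to genetic
#'   distance, in cM/Mb (default 4, a rice-typical genome-wide average).
#' @param dominance Dominance coefficient of the QTL on the additive scale
#'   (0 = purely additive, the default; 1 = complete dominance).
#' @param trait_mean Baseline trait value of the heterozygote (default 0.6,
#'   an RSL-like unitless ratio).
#' @param residual_sd Environmental standard deviation of the trait
#'   (default 0.15).
#' @param seed Integer seed feeding the named per-stage random streams.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cross()], [simulate_pool_depths()]
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 200, bulk_size = 20, n_snps_per_chrom = 500)
#' cfg
sim_config <- function(n_lines = 983,
                       bulk_size = 40,
                       n_chrom = 1,
                       chrom_length_bp = 30e6,
                       n_snps_per_chrom = 5000,
                       qtl_chrom = "chr1",
                       qtl_pos_bp = NULL,
                       qtl_pve = 0.249,
                       mean_depth = 27.6,
                       depth_model = c("poisson", "fixed"),
                       cm_per_mb = 4,
                       dominance = 0,
                       trait_mean = 0.6,
                       residual_sd = 0.15,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  qtl_pos_bp <- qtl_pos_bp %||% round(chrom_length_bp / 2)

  if (!is_count(n_lines)) abort_config("n_lines", "must be a positive integer")
  if (!is_count(bulk_size)) abort_config("bulk_size", "must be a positive integer")
  if (2 * bulk_size > n_lines)
    abort_config("bulk_size", "requires 2 * bulk_size <= n_lines")
  if (!is_count(n_chrom)) abort_config("n_chrom", "must be a positive integer")
  if (!is.numeric(chrom_length_bp) || chrom_length_bp < 1)
    abort_config("chrom_length_bp", "must be a positive length in bp")
  if (!is_count(n_snps_per_chrom))
    abort_config("n_snps_per_chrom", "must be a positive integer")
  chroms <- paste0("chr", seq_len(n_chrom))
  if (!qtl_chrom %in% chroms)
    abort_config("qtl_chrom", sprintf("must be one of %s", paste(chroms, collapse = ", ")))
  if (!is.numeric(qtl_pos_bp) || qtl_pos_bp < 1 || qtl_pos_bp > chrom_length_bp)
    abort_config("qtl_pos_bp", "must lie within [1, chrom_length_bp]")
  if (!is.numeric(qtl_pve) || qtl_pve < 0 || qtl_pve >= 1)
    abort_config("qtl_pve", "must lie in [0, 1)")
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    abort_config("mean_depth", "must be > 0")
  if (!is.numeric(cm_per_mb) || cm_per_mb < 0)
    abort_config("cm_per_mb", "must be >= 0")
  if (!is.numeric(residual_sd) || residual_sd <= 0)
    abort_config("residual_sd", "must be > 0")

  structure(
    list(
      n_lines = as.integer(n_lines), bulk_size = as.integer(bulk_size),
      n_chrom = as.integer(n_chrom), chrom_length_bp = chrom_length_bp,
      n_snps_per_chrom = as.integer(n_snps_per_chrom),
      qtl_chrom = qtl_chrom, qtl_pos_bp = qtl_pos_bp, qtl_pve = qtl_pve,
      mean_depth = mean_depth, depth_model = depth_model,
      cm_per_mb = cm_per_mb, dominance = dominance,
      trait_mean = trait_mean, residual_sd = residual_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  F2 lines: %d; bulks: 2 x %d\n", x$n_lines, x$bulk_size))
  cat(sprintf("  genome: %d chromosome(s) x %.1f Mb, %d SNPs each (%.1f cM/Mb)\n",
              x$n_chrom, x$chrom_length_bp / 1e6, x$n_snps_per_chrom, x$cm_per_mb))
  cat(sprintf("  QTL: %s:%s, PVE = %.3f, dominance = %.2f\n",
              x$qtl_chrom, format(x$qtl_pos_bp, big.mark = ","),
              x$qtl_pve, x$dominance))
  cat(sprintf("  depth: %s, mean %.1fx per pool; seed = %d\n",
              x$depth_model, x$mean_depth, x$seed))
  invisible(x)
}
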