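#' Simulate pooled sequencing allele depths for the two bulks
#'
#' Emulates pooled whole-genome sequencing of the two extreme bulks. For
#' each SNP and pool, the true pool alt-allele frequency is the mean allele
#' dosage over the pooled lines, `f = sum(genotype codes) / (2 * bulk_size)`;
#' total read depth is drawn from the configured depth model (Poisson with
#' the configured mean, truncated at >= 1, by default), and the alt read
#' count is Binomial(depth, f). No sequencing-error model is applied: reads
#' sample chromosomes in the pool exactly.
#'
#' @param dataset A `sim_dataset` from [simulate_cross()].
#' @param pools A data frame with `line_id` and `pool` (`"T"`, `"S"`,
#'   `"none"`), e.g. from [select_bulks()].
#' @param config A [sim_config()]; defaults to the one stored in `dataset`.
#' @return A tibble of allele-depth records: `chrom`, `pos`, `ref`, `alt`,
#'   `t_ref`, `t_alt`, `s_ref`, `s_alt`, plus the true pool frequencies
#'   `true_f_t`, `true_f_s` (truth columns, dropped on export).
#' @export
#' @examples
#' ds <- simulate_cross(sim_config(n_lines = 100, bulk_size = 10,
#'                                 n_snps_per_chrom = 100))
#' pools <- select_bulks(ds$phenotypes, 10)
#' simulate_pool_depths(ds, pools)
simulate_pool_depths <- function(dataset, pools, config = dataset$config) {
  stopifnot(inherits(dataset, "sim_dataset"),
            all(c("line_id", "pool") %in% names(pools)))
  if (!any(pools$pool == "T") || !any(pools$pool == "S"))
    abort("pools must contain lines labelled both \"T\" and \"S\"")
  set.seed(stage_seed(config$seed, "depths"))

  g <- dataset$genotypes
  t_lines <- pools$line_id[pools$pool == "T"]
  s_lines <- pools$line_id[pools$pool == "S"]
  f_t <- colSums(g[t_lines, , drop = FALSE]) / (2 * length(t_lines))
  f_s <- colSums(g[s_lines, , drop = FALSE]) / (2 * length(s_lines))

  n <- ncol(g)
  draw_depth <- function(n) {
    if (config$depth_model == "fixed") return(rep(max(1L, round(config$mean_depth)), n))
    d <- rpois(n, config$mean_depth)
    while (any(zero <- d == 0L)) d[zero] <- rpois(sum(zero), config$mean_depth)
    d
  }
  d_t <- draw_depth(n)
  d_s <- draw_depth(n)
  alt_t <- rbinom(n, d_t, f_t)
  alt_s <- rbinom(n, d_s, f_s)

  dplyr::bind_cols(
    dataset$snps[, c("chrom", "pos", "ref", "alt")],
    tibble(t_ref = d_t - alt_t, t_alt = alt_t,
           s_ref = d_s - alt_s, s_alt = alt_s,
           true_f_t = unname(f_t), true_f_s = unname(f_s))
  )
}
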