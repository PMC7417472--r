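#' SNP-index of a pool at a marker
#'
#' The SNP-index is the proportion of reads at a SNP that carry the allele
#' differing from the reference sequence: `alt / (ref + alt)`. Markers whose
#' total depth is below `min_depth` are uninformative and return `NA`
#' (filtered).
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @param min_depth Minimum total depth for a defined index (default 7).
#' @return Numeric vector in `[0, 1]`, `NA` where depth < `min_depth`.
#' @export
#' @examples
#' snp_index(10, 10)        # 0.5
#' snp_index(0, 20)         # 1
#' snp_index(2, 1)          # NA: depth 3 < 7
snp_index <- function(ref_count, alt_count, min_depth = 7) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    abort("read counts must be non-negative")
  depth <- ref_count + alt_count
  out <- alt_count / depth
  out[depth < min_depth] <- NA_real_
  out
}

#' Delta SNP-index between the two pools
#'
#' Difference of the pool SNP-indices at a marker. The default convention is
#' S-pool minus T-pool (`"s_minus_t"`): the sensitive pool's index minus the
#' tolerant pool's. Away from a causal locus both pools sample the same
#' 1:2:1 segregation, so the expectation is 0; near a causal locus the pools
#' are enriched for opposite alleles and the difference approaches +/-1.
#'
#' @param index_t,index_s Pool SNP-indices (vectorized).
#' @param convention `"s_minus_t"` (default) or `"t_minus_s"`.
#' @return Values in `[-1, 1]`.
#' @export
#' @examples
#' delta_snp_index(0.8, 0.3)   # -0.5
delta_snp_index <- function(index_t, index_s,
                            convention = c("s_minus_t", "t_minus_s")) {
  convention <- match.arg(convention)
  if (convention == "s_minus_t") index_s - index_t else index_t - index_s
}

#' Per-pool base frequencies at a marker
#'
#' Converts ref/alt read counts at a biallelic SNP into the four-base
#' frequency vector (A, C, G, T) used by the Euclidean-distance statistic.
#'
#' @param ref_base,alt_base Single bases in `A/C/G/T`, `ref_base != alt_base`.
#' @param ref_count,alt_count Read counts for the two alleles.
#' @return Named numeric vector of length 4 summing to 1.
#' @export
#' @examples
#' base_frequencies("A", "C", 7, 3)
base_frequencies <- function(ref_base, alt_base, ref_count, alt_count) {
  bases <- c("A", "C", "G", "T")
  stopifnot(ref_base %in% bases, alt_base %in% bases, ref_base != alt_base)
  depth <- ref_count + alt_count
  if (depth <= 0) abort("cannot form base frequencies at zero depth")
  out <- setNames(numeric(4), bases)
  out[ref_base] <- ref_count / depth
  out[alt_base] <- alt_count / depth
  out
}

#' Euclidean distance between pool base-frequency vectors
#'
#' The ED statistic at a SNP is the Euclidean distance between the two
#' pools' four-base frequency vectors:
#' `ED = sqrt((A_T-A_S)^2 + (C_T-C_S)^2 + (G_T-G_S)^2 + (T_T-T_S)^2)`.
#' It is 0 when the pools have identical base composition and reaches
#' `sqrt(2)` when the pools are fixed for different alleles. For a biallelic
#' site this reduces to `sqrt(2) * |p_T - p_S|` with `p` the alt-allele
#' frequency.
#'
#' @param freq_t,freq_s Numeric vectors of length 4 (A, C, G, T fractions),
#'   each summing to 1.
#' @return The ED value, in `[0, sqrt(2)]` for biallelic sites.
#' @export
#' @examples
#' euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))  # sqrt(2)
#' euclidean_distance(c(0.7, 0.3, 0, 0), c(0.4, 0.6, 0, 0))  # sqrt(0.18)
euclidean_distance <- function(freq_t, freq_s) {
  for (f in list(freq_t, freq_s)) {
    if (length(f) != 4 || any(f < 0) || any(f > 1))
      abort("base frequencies must be 4 fractions in [0, 1]")
    if (abs(sum(f) - 1) > 1e-8)
      abort("base frequencies must sum to 1")
  }
  sqrt(sum((freq_t - freq_s)^2))
}

#' Build the per-SNP scan table from allele depths
#'
#' Computes, for every allele-depth record with sufficient depth in both
#' pools, the pool SNP-indices, the delta SNP-index and the ED statistic.
#' ED is computed from the four-base frequency vectors of the two pools;
#' for biallelic records this equals `sqrt(2) * |snp_index_t - snp_index_s|`
#' and the closed form is used. Records in which either pool is below
#' `min_depth` are dropped with a message.
#'
#' @param depths Allele-depth tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `t_ref`, `t_alt`, `s_ref`, `s_alt` (from
#'   [simulate_pool_depths()] or [read_allele_depths()]).
#' @param min_depth Minimum per-pool depth (default 7).
#' @param delta_convention Sign convention of [delta_snp_index()].
#' @return A `bsa_scan` tibble sorted by `(chrom, pos)` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `t_depth`, `s_depth`, `snp_index_t`,
#'   `snp_index_s`, `delta_snp_index`, `ed`.
#' @export
compute_scan <- function(depths, min_depth = 7,
                         delta_convention = c("s_minus_t", "t_minus_s")) {
  delta_convention <- match.arg(delta_convention)
  need <- c("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "s_ref", "s_alt")
  stopifnot(all(need %in% names(depths)))

  out <- as_tibble(depths) |>
    mutate(t_depth = .data$t_ref + .data$t_alt,
           s_depth = .data$s_ref + .data$s_alt)
  low <- out$t_depth < min_depth | out$s_depth < min_depth
  if (any(low))
    inform(sprintf("%d marker(s) below min_depth %d dropped from the scan",
                   sum(low), min_depth))
  out <- out[!low, , drop = FALSE]

  out <- out |>
    mutate(
      snp_index_t = snp_index(.data$t_ref, .data$t_alt, min_depth = min_depth),
      snp_index_s = snp_index(.data$s_ref, .data$s_alt, min_depth = min_depth),
      delta_snp_index = delta_snp_index(.data$snp_index_t, .data$snp_index_s,
                                        convention = delta_convention),
      ed = sqrt(2) * abs(.data$snp_index_t - .data$snp_index_s)
    ) |>
    select(all_of(c("chrom", "pos", "ref", "alt", "t_depth", "s_depth",
                    "snp_index_t", "snp_index_s", "delta_snp_index", "ed"))) |>
    arrange(.data$chrom, .data$pos)
  class(out) <- c("bsa_scan", class(out))
  attr(out, "delta_convention") <- delta_convention
  out
}
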