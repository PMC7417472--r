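#' Simulate an F2 population with one additive QTL
#'
#' Generates F2 genotypes by dropping two recombinant gametes per line along
#' each chromosome, then assigns each line a quantitative trait controlled by
#' a single QTL plus Gaussian noise. Marker-to-marker recombination fractions
#' come from the Haldane map function applied to physical distance at a fixed
#' cM/Mb rate, so each gamete is a two-state Markov chain along the marker
#' map and unlinked chromosomes segregate independently. Genotypes are coded
#' 0/1/2 as the count of tolerant-parent alleles, so expected segregation at
#' every marker is 1:2:1.
#'
#' The QTL is placed at the marker nearest `qtl_pos_bp`. Writing `a` for the
#' additive effect, genotype values are `-a`, `d*a`, `+a` for 0/1/2 copies
#' (`d` the dominance coefficient, 0 by default), and `a` is chosen so that
#' the genetic variance under 1:2:1 segregation is the requested fraction
#' `qtl_pve` of the total phenotypic variance.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{snps}{tibble of markers: `chrom`, `pos`, `snp_id`, `ref`, `alt`
#'       (the tolerant-parent allele is always `alt`), `is_qtl`.}
#'     \item{genotypes}{integer matrix, lines x markers, values 0/1/2
#'       counting tolerant-parent alleles.}
#'     \item{phenotypes}{tibble `line_id`, `value` (RSL-like unitless ratio).}
#'     \item{qtl_snp_id}{id of the causal marker.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' ds <- simulate_cross(sim_config(n_lines = 100, n_snps_per_chrom = 200))
#' dim(ds$genotypes)
simulate_cross <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(stage_seed(config$seed, "cross"))

  chroms <- paste0("chr", seq_len(config$n_chrom))
  n_mk <- config$n_snps_per_chrom
  spacing <- config$chrom_length_bp / n_mk
  pos <- pmin(pmax(round(spacing * (seq_len(n_mk) - 0.5)), 1), config$chrom_length_bp)

  base_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                       ncol = 2, byrow = TRUE)

  snps <- purrr::map_dfr(chroms, function(ch) {
    pair <- base_pairs[sample.int(nrow(base_pairs), n_mk, replace = TRUE), , drop = FALSE]
    tibble(chrom = ch, pos = pos,
           snp_id = sprintf("%s_%09d", ch, pos),
           ref = pair[, 1], alt = pair[, 2])
  })

  # recombination fraction between adjacent markers (Haldane, physical->cM)
  rec_frac <- function(delta_bp) {
    d_morgan <- delta_bp / 1e6 * config$cm_per_mb / 100
    0.5 * (1 - exp(-2 * d_morgan))
  }

  one_gamete_set <- function() {
    # lines x markers matrix of {0,1} alleles for one gamete per line
    g <- matrix(0L, nrow = config$n_lines, ncol = n_mk * config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
      cols <- (ci - 1L) * n_mk + seq_len(n_mk)
      r <- rec_frac(diff(pos))
      a <- matrix(0L, nrow = config$n_lines, ncol = n_mk)
      a[, 1] <- as.integer(runif(config$n_lines) < 0.5)
      for (j in seq_len(n_mk - 1L)) {
        flip <- runif(config$n_lines) < r[j]
        a[, j + 1L] <- ifelse(flip, 1L - a[, j], a[, j])
      }
      g[, cols] <- a
    }
    g
  }

  genotypes <- one_gamete_set() + one_gamete_set()
  colnames(genotypes) <- snps$snp_id
  rownames(genotypes) <- sprintf("L%04d", seq_len(config$n_lines))

  # causal marker = nearest to the requested QTL position
  cand <- which(snps$chrom == config$qtl_chrom)
  qtl_idx <- cand[which.min(abs(snps$pos[cand] - config$qtl_pos_bp))]
  snps$is_qtl <- seq_len(nrow(snps)) == qtl_idx

  # additive effect scaled so var_QTL / var_total = qtl_pve
  dom <- config$dominance
  sigma <- config$residual_sd
  pve <- config$qtl_pve
  a <- if (pve > 0) sigma * sqrt(pve / ((1 - pve) * (0.5 + 0.25 * dom^2))) else 0
  gq <- genotypes[, qtl_idx]
  gval <- a * (gq - 1)
  gval[gq == 1L] <- dom * a
  value <- config$trait_mean + gval + rnorm(config$n_lines, 0, sigma)

  structure(
    list(
      snps = snps,
      genotypes = genotypes,
      phenotypes = tibble(line_id = rownames(genotypes), value = value),
      qtl_snp_id = snps$snp_id[qtl_idx],
      config = config
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  cat(sprintf("  %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$config$n_chrom))
  cat(sprintf("  QTL marker: %s (PVE %.3f)\n", x$qtl_snp_id, x$config$qtl_pve))
  invisible(x)
}

#' Select extreme-phenotype bulks
#'
#' Assigns the `bulk_size` lines with the largest trait values to the
#' tolerant pool (`"T"`) and the `bulk_size` smallest to the sensitive pool
#' (`"S"`); all other lines are labelled `"none"`. Ordering is a stable sort
#' by `(value, line_id)`, so ties are resolved deterministically by line id;
#' a tie spanning a selection boundary raises a warning because lines with
#' the boundary value are then included or excluded by id order alone.
#'
#' @param phenotypes A data frame with columns `line_id` and `value`
#'   (one row per line), e.g. the `phenotypes` element of a
#'   [simulate_cross()] dataset.
#' @param bulk_size Lines per pool; `2 * bulk_size` must not exceed the
#'   number of lines.
#' @return The input as a tibble with an added `pool` column in
#'   `c("T", "S", "none")`.
#' @export
#' @examples
#' ph <- tibble::tibble(line_id = paste0("L", 1:6), value = c(1, 2, 3, 4, 5, 6))
#' select_bulks(ph, bulk_size = 2)
select_bulks <- function(phenotypes, bulk_size) {
  stopifnot(is.data.frame(phenotypes),
            all(c("line_id", "value") %in% names(phenotypes)))
  if (!is_count(bulk_size)) abort_config("bulk_size", "must be a positive integer")
  n <- nrow(phenotypes)
  if (2 * bulk_size > n)
    abort(sprintf("cannot form two bulks of %d from %d lines", bulk_size, n))
  if (anyNA(phenotypes$value))
    abort("missing phenotype values among selectable lines")

  ord <- order(phenotypes$value, phenotypes$line_id)  # stable, ascending
  s_idx <- ord[seq_len(bulk_size)]
  t_idx <- ord[seq.int(n - bulk_size + 1L, n)]

  v <- phenotypes$value
  if (v[ord[bulk_size]] == v[ord[bulk_size + 1L]])
    warn("ties span the S-pool selection boundary; resolved by line-id order")
  if (v[ord[n - bulk_size + 1L]] == v[ord[n - bulk_size]])
    warn("ties span the T-pool selection boundary; resolved by line-id order")

  out <- as_tibble(phenotypes)
  out$pool <- "none"
  out$pool[s_idx] <- "S"
  out$pool[t_idx] <- "T"
  out
}
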