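#' Smooth the genome-scan statistics with a tricube sliding window
#'
#' Fits each statistic at every SNP as the tricube-weighted mean over all
#' SNPs within a fixed physical half-width on the same chromosome (windows
#' never span chromosomes). The ED branch first raises the raw per-SNP ED to
#' a power (default 4) to suppress background noise, then smooths; the delta
#' branch smooths the delta SNP-index directly. Weights are
#' `w = (1 - (|d|/h)^3)^3` for distance `d` within half-width `h`, so the
#' kernel preserves constants and has compact support. Windows holding fewer
#' than `min_window_snps` markers yield `NA` (logged).
#'
#' @param scan A `bsa_scan` tibble from [compute_scan()] (or any tibble with
#'   `chrom`, `pos` and the required statistic columns), sorted by position
#'   within chromosome.
#' @param statistic `"both"` (default), `"delta"` or `"ed"`.
#' @param half_width_bp Window half-width in bp (default 1 Mb).
#' @param ed_power Power applied to raw ED before smoothing (default 4).
#' @param min_window_snps Minimum markers per window (default 10).
#' @return The input with `fitted_delta` and/or `fitted_ed` columns added.
#'   `fitted_ed` is the smoothed `ed^ed_power`, on that powered scale.
#' @export
#' @examples
#' ds <- simulate_cross(sim_config(n_lines = 120, bulk_size = 12,
#'                                 n_snps_per_chrom = 300))
#' pools <- select_bulks(ds$phenotypes, 12)
#' scan <- compute_scan(simulate_pool_depths(ds, pools))
#' fit <- fit_scan(scan, half_width_bp = 2e6)
fit_scan <- function(scan, statistic = c("both", "delta", "ed"),
                     half_width_bp = 1e6, ed_power = 4,
                     min_window_snps = 10) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("chrom", "pos") %in% names(scan)),
            half_width_bp > 0, min_window_snps >= 1)
  do_delta <- statistic %in% c("both", "delta")
  do_ed <- statistic %in% c("both", "ed")
  if (do_delta) stopifnot("delta_snp_index" %in% names(scan))
  if (do_ed) stopifnot("ed" %in% names(scan))

  out <- as_tibble(scan)
  if (is.unsorted(order(out$chrom, out$pos)))
    out <- arrange(out, .data$chrom, .data$pos)

  smooth_one <- function(pos, y, h) {
    n <- length(pos)
    fitted <- rep(NA_real_, n)
    lo <- findInterval(pos - h - 1, pos) + 1L  # first j with pos[j] >= pos[i] - h
    hi <- findInterval(pos + h, pos)           # last j with pos[j] <= pos[i] + h
    for (i in seq_len(n)) {
      j <- lo[i]:hi[i]
      if (length(j) < min_window_snps) next
      w <- (1 - (abs(pos[j] - pos[i]) / h)^3)^3
      sw <- sum(w)
      if (sw > 0) fitted[i] <- sum(w * y[j]) / sw
    }
    fitted
  }

  pieces <- split(seq_len(nrow(out)), out$chrom)
  if (do_delta) out$fitted_delta <- NA_real_
  if (do_ed) out$fitted_ed <- NA_real_
  for (idx in pieces) {
    pos <- out$pos[idx]
    if (do_delta)
      out$fitted_delta[idx] <- smooth_one(pos, out$delta_snp_index[idx], half_width_bp)
    if (do_ed)
      out$fitted_ed[idx] <- smooth_one(pos, out$ed[idx]^ed_power, half_width_bp)
  }
  n_na <- sum(if (do_delta) is.na(out$fitted_delta) else 0) +
    sum(if (do_ed) is.na(out$fitted_ed) else 0)
  if (n_na > 0)
    inform(sprintf("%d fitted value(s) undefined (window below %d SNPs)",
                   n_na, min_window_snps))
  class(out) <- unique(c("bsa_scan", class(out)))
  attr(out, "half_width_bp") <- half_width_bp
  attr(out, "ed_power") <- ed_power
  out
}
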