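#' Simulated null confidence bounds for the delta SNP-index
#'
#' Under the no-QTL null each pool of `bulk_size` F2 lines samples
#' `2 * bulk_size` chromosomes whose alleles are Bernoulli(0.5) (1:2:1 F2
#' segregation), and the observed pool SNP-indices add binomial read
#' sampling at the marker's depth. This function simulates that two-stage
#' null and returns the 95th and 99th percentiles of `|delta SNP-index|` as
#' depth-conditional significance bounds.
#'
#' Each marker's depth pair is mapped to an effective per-pool depth
#' `d_eff = 2 / (1/depth_t + 1/depth_s)` (the harmonic mean, which preserves
#' the read-sampling variance `~ 1/depth_t + 1/depth_s`), simulation runs
#' once per unique effective depth, and the resulting bound-versus-depth
#' curves are made monotone non-increasing by isotonic regression (pooled
#' adjacent-violators averaging over the simulated grid) before lookup.
#'
#' @param depth_t,depth_s Per-marker read depths of the two pools
#'   (vectorized, recycled to common length).
#' @param bulk_size Lines per pool.
#' @param n_sims Null simulations per depth grid point (default 10000).
#' @param seed Integer seed.
#' @return A tibble with one row per input marker: `d_eff`, `ci95`, `ci99`.
#' @export
#' @examples
#' delta_null_bounds(30, 30, bulk_size = 40, n_sims = 2000, seed = 1)
delta_null_bounds <- function(depth_t, depth_s, bulk_size,
                              n_sims = 10000, seed = 1L) {
  if (n_sims < 1000) abort("n_sims must be at least 1000")
  if (!is_count(bulk_size)) abort_config("bulk_size", "must be a positive integer")
  n <- max(length(depth_t), length(depth_s))
  depth_t <- rep_len(depth_t, n)
  depth_s <- rep_len(depth_s, n)
  if (any(depth_t < 1) || any(depth_s < 1)) abort("depths must be >= 1")

  d_eff <- pmax(1L, as.integer(round(2 / (1 / depth_t + 1 / depth_s))))
  grid <- sort(unique(d_eff))
  n_chrom_pool <- 2L * bulk_size

  set.seed(stage_seed(seed, "null"))
  q95 <- q99 <- numeric(length(grid))
  for (k in seq_along(grid)) {
    d <- grid[k]
    f_t <- rbinom(n_sims, n_chrom_pool, 0.5) / n_chrom_pool
    f_s <- rbinom(n_sims, n_chrom_pool, 0.5) / n_chrom_pool
    idx_t <- rbinom(n_sims, d, f_t) / d
    idx_s <- rbinom(n_sims, d, f_s) / d
    abs_delta <- abs(idx_s - idx_t)
    q95[k] <- quantile(abs_delta, 0.95, names = FALSE)
    q99[k] <- quantile(abs_delta, 0.99, names = FALSE)
  }
  # enforce bounds non-increasing in depth (pooled adjacent-violators)
  mono_dec <- function(y) {
    if (length(y) > 1) -isoreg(seq_along(y), -y)$yf else y
  }
  q95 <- mono_dec(q95)
  q99 <- mono_dec(q99)

  pos <- match(d_eff, grid)
  tibble(d_eff = d_eff, ci95 = q95[pos], ci99 = q99[pos])
}

#' Simulated genome-wide null threshold for the fitted ED statistic
#'
#' Builds the ED significance cutoff from no-QTL null genome scans. Each
#' replicate simulates random pools of `bulk_size` F2 lines over the
#' observed marker map: every pooled chromosome is a two-state Markov chain
#' along the markers (Haldane recombination from physical distance at
#' `cm_per_mb`), pool allele frequencies are the chain means, read counts
#' are binomial at the observed per-marker depths, and the resulting raw ED
#' values are powered and smoothed exactly like the observed scan. The
#' threshold is a quantile (default 0.95) of the per-replicate genome-wide
#' maxima — an empirical genome-wide error rate in the spirit of
#' permutation thresholds for QTL scans.
#'
#' Unlike [ed_threshold()], which estimates background location/scale from
#' the observed fitted values, this null-simulation cutoff stays valid when
#' a strong QTL's linkage footprint spans much of a (small) genome and
#' contaminates the observed background; on desk-scale simulated genomes it
#' is the pipeline default.
#'
#' @param scan Scan tibble with `chrom`, `pos`, `t_depth`, `s_depth`.
#' @param bulk_size Lines per pool.
#' @param cm_per_mb Physical-to-genetic rate used for the null gamete
#'   chains (default 4).
#' @param half_width_bp,ed_power,min_window_snps Smoothing parameters; must
#'   match those used for the observed scan (see [fit_scan()]).
#' @param n_reps Null genome scans (default 10).
#' @param prob Quantile of the genome-wide maxima (default 0.95).
#' @param seed Integer seed.
#' @return The scalar threshold on the fitted (powered, smoothed) ED scale.
#' @export
ed_null_threshold <- function(scan, bulk_size, cm_per_mb = 4,
                              half_width_bp = 1e6, ed_power = 4,
                              min_window_snps = 10,
                              n_reps = 10, prob = 0.95, seed = 1L) {
  stopifnot(all(c("chrom", "pos", "t_depth", "s_depth") %in% names(scan)),
            n_reps >= 2)
  scan <- arrange(as_tibble(scan), .data$chrom, .data$pos)
  set.seed(stage_seed(seed, "null") + 1L)

  n_chr_pool <- 2L * bulk_size  # chromosomes sampled per pool
  pieces <- split(seq_len(nrow(scan)), scan$chrom)

  null_freq <- function(pos) {
    # n_chr_pool independent gamete chains along the marker map
    d_morgan <- diff(pos) / 1e6 * cm_per_mb / 100
    r <- 0.5 * (1 - exp(-2 * d_morgan))
    a <- matrix(0L, nrow = n_chr_pool, ncol = length(pos))
    a[, 1] <- as.integer(runif(n_chr_pool) < 0.5)
    for (j in seq_along(r)) {
      flip <- runif(n_chr_pool) < r[j]
      a[, j + 1L] <- ifelse(flip, 1L - a[, j], a[, j])
    }
    colMeans(a)
  }

  maxima <- vapply(seq_len(n_reps), function(rep) {
    fit_max <- -Inf
    for (idx in pieces) {
      pos <- scan$pos[idx]
      f_t <- null_freq(pos)
      f_s <- null_freq(pos)
      d_t <- scan$t_depth[idx]
      d_s <- scan$s_depth[idx]
      idx_t <- rbinom(length(pos), d_t, f_t) / d_t
      idx_s <- rbinom(length(pos), d_s, f_s) / d_s
      ed_raw <- sqrt(2) * abs(idx_t - idx_s)
      sm <- suppressMessages(
        fit_scan(tibble(chrom = "c", pos = pos, ed = ed_raw),
                 statistic = "ed", half_width_bp = half_width_bp,
                 ed_power = ed_power, min_window_snps = min_window_snps))
      fit_max <- max(fit_max, sm$fitted_ed, na.rm = TRUE)
    }
    fit_max
  }, numeric(1))
  quantile(maxima, prob, names = FALSE)
}

#' Genome-wide robust threshold for the fitted ED statistic
#'
#' A robust location/scale cutoff on the genome-wide distribution of fitted
#' (powered, smoothed) ED values: `median + multiplier * SD`, where the SD
#' is the root mean squared deviation about the median. Fitted values that
#' are `NA` (undersized windows) are ignored.
#'
#' @param fitted_ed Fitted ED values across the genome (>= 100 required).
#' @param multiplier Number of SDs above the median (default 3).
#' @return The scalar threshold.
#' @export
#' @examples
#' ed_threshold(abs(rnorm(1000)))
ed_threshold <- function(fitted_ed, multiplier = 3) {
  x <- fitted_ed[!is.na(fitted_ed)]
  if (length(x) < 100)
    abort("ed_threshold needs at least 100 fitted values")
  med <- median(x)
  s <- sqrt(mean((x - med)^2))
  if (s == 0) {
    warn("all fitted ED values are equal: threshold equals that value; no region can exceed it")
    return(med)
  }
  med + multiplier * s
}
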