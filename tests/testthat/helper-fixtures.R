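# Shared fixtures and independent brute-force oracles used across tests.

# small simulated experiment: cross + bulks + depths
tiny_experiment <- function(seed = 1, n_lines = 120, bulk_size = 15,
                            n_snps = 300, n_chrom = 1,
                            chrom_length_bp = 10e6, qtl_pve = 0.249, ...) {
  cfg <- sim_config(n_lines = n_lines, bulk_size = bulk_size,
                    n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                    n_snps_per_chrom = n_snps, qtl_pve = qtl_pve,
                    seed = seed, ...)
  ds <- simulate_cross(cfg)
  pools <- select_bulks(ds$phenotypes, cfg$bulk_size)
  depths <- suppressMessages(simulate_pool_depths(ds, pools))
  list(cfg = cfg, ds = ds, pools = pools, depths = depths)
}

# hand-built sim_dataset with fully controlled genotypes (lines x snps)
manual_dataset <- function(genotypes, chrom = "chr1", seed = 1,
                           mean_depth = 30, depth_model = "fixed") {
  n_snps <- ncol(genotypes)
  n_lines <- nrow(genotypes)
  pos <- seq(1000, by = 1000, length.out = n_snps)
  snps <- tibble::tibble(chrom = chrom, pos = pos,
                         snp_id = sprintf("%s_%09d", chrom, pos),
                         ref = "A", alt = "G",
                         is_qtl = c(TRUE, rep(FALSE, n_snps - 1)))
  colnames(genotypes) <- snps$snp_id
  rownames(genotypes) <- sprintf("L%04d", seq_len(n_lines))
  cfg <- sim_config(n_lines = n_lines, bulk_size = floor(n_lines / 2),
                    n_chrom = 1, chrom_length_bp = max(pos),
                    n_snps_per_chrom = n_snps, mean_depth = mean_depth,
                    depth_model = depth_model, seed = seed)
  structure(list(snps = snps, genotypes = genotypes,
                 phenotypes = tibble::tibble(
                   line_id = rownames(genotypes),
                   value = seq_len(n_lines)),
                 qtl_snp_id = snps$snp_id[1], config = cfg),
            class = "sim_dataset")
}

# brute-force tricube kernel smoother (independent of fit_scan internals)
oracle_tricube <- function(pos, y, h, min_n = 1) {
  vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    in_win <- d <= h
    if (sum(in_win) < min_n) return(NA_real_)
    w <- (1 - (d[in_win] / h)^3)^3
    if (sum(w) == 0) return(NA_real_)
    sum(w * y[in_win]) / sum(w)
  }, numeric(1))
}

# brute-force membership-count Venn oracle
oracle_venn_count <- function(sets, members) {
  universe <- unique(unlist(sets))
  sum(vapply(universe, function(id) {
    all(vapply(names(sets), function(nm)
      (id %in% sets[[nm]]) == (nm %in% members), logical(1)))
  }, logical(1)))
}

# brute-force any-overlap gene scan
oracle_genes_overlap <- function(genes, chrom, start, end) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    genes$chrom[i] == chrom &&
      max(genes$start[i], start) <= min(genes$end[i], end)
  }, logical(1))
  sort(genes$gene_id[hit])
}

# brute-force region intersection on a small integer grid
oracle_intersect_grid <- function(a, b, grid_max = 1000) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- list()
  for (ch in chroms) {
    cover <- function(r) {
      v <- logical(grid_max)
      for (i in which(r$chrom == ch))
        v[r$start_bp[i]:r$end_bp[i]] <- TRUE
      v
    }
    both <- cover(a) & cover(b)
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (ends[k] > starts[k])  # positive length only
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start_bp = starts[k], end_bp = ends[k])
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric()))
  dplyr::arrange(dplyr::bind_rows(out), chrom, start_bp)
}

# brute-force region caller from a pass vector: walk passing SNPs in order,
# break a region when the chromosome changes or when the SNPs are not
# index-consecutive and the bp gap exceeds merge_gap
oracle_call_runs <- function(chrom, pos, pass, merge_gap) {
  idx <- which(pass)
  if (length(idx) == 0)
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric()))
  regions <- list()
  cur <- list(chrom = chrom[idx[1]], start = pos[idx[1]], end = pos[idx[1]],
              i = idx[1])
  for (i in idx[-1]) {
    new_region <- chrom[i] != cur$chrom ||
      (i != cur$i + 1 && pos[i] - cur$end > merge_gap)
    if (new_region) {
      regions[[length(regions) + 1]] <- cur
      cur <- list(chrom = chrom[i], start = pos[i], end = pos[i], i = i)
    } else {
      cur$end <- pos[i]; cur$i <- i
    }
  }
  regions[[length(regions) + 1]] <- cur
  dplyr::bind_rows(lapply(regions, function(r)
    tibble::tibble(chrom = r$chrom, start_bp = r$start, end_bp = r$end)))
}
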