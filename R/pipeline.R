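#' Assemble a full pipeline configuration
#'
#' Collects every stage's tunables into one object: the synthetic-cross
#' generator, the marker filters, the smoothing kernel, the thresholding
#' rules and the candidate-gene contrasts. One `seed` feeds named per-stage
#' random streams so stages are independently reproducible; all defaults are
#' materialized here and echoed into the run manifest.
#'
#' @param seed Integer seed for the whole run.
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param filters List: `min_depth` (per-pool, default 7),
#'   `max_depth_quantile` (default 0.99).
#' @param smoothing List: `half_width_bp` (default 1 Mb), `ed_power`
#'   (default 4), `min_window_snps` (default 10).
#' @param thresholds List: `delta_ci_level` (`"ci95"` or `"ci99"`),
#'   `ed_threshold_method` (`"null_sim"`, the default, for
#'   [ed_null_threshold()]; `"robust"` for [ed_threshold()]),
#'   `ed_null_reps`/`ed_null_prob` (null-scan replicates and maxima
#'   quantile), `ed_multiplier` (default 3, robust method), `n_sims`
#'   (default 10000), `merge_gap_bp` (default 500 kb), `round_to_bp`
#'   (default 10 kb).
#' @param candidates List: `contrasts` (default `IRvsTIR`, `WGvsTWG`),
#'   `n_genes` and `n_causal` for the simulated annotation/DEG stage.
#' @param io List of optional input paths for non-simulated runs:
#'   `depths`, `gene_models`, `deg_table`.
#' @param delta_convention Sign convention of the delta SNP-index.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(),
                            filters = list(),
                            smoothing = list(),
                            thresholds = list(),
                            candidates = list(),
                            io = list(),
                            delta_convention = "s_minus_t") {
  sim$seed <- as.integer(seed)
  cfg <- list(
    seed = as.integer(seed),
    sim = sim,
    filters = modifyList(list(min_depth = 7, max_depth_quantile = 0.99),
                         filters),
    smoothing = modifyList(list(half_width_bp = 1e6, ed_power = 4,
                                min_window_snps = 10), smoothing),
    thresholds = modifyList(list(delta_ci_level = "ci95", ed_multiplier = 3,
                                 ed_threshold_method = "null_sim",
                                 ed_null_reps = 10, ed_null_prob = 0.95,
                                 n_sims = 10000, merge_gap_bp = 5e5,
                                 round_to_bp = 1e4), thresholds),
    candidates = modifyList(list(contrasts = c("IRvsTIR", "WGvsTWG"),
                                 n_genes = 200, n_causal = 5), candidates),
    io = modifyList(list(depths = NULL, gene_models = NULL, deg_table = NULL),
                    io),
    delta_convention = delta_convention
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full BSA pipeline: simulate, scan, call regions, triage genes
#'
#' Executes the stages in order — synthetic-data generation (optional),
#' genome scan (indices, smoothing, null bounds, thresholds, region calling,
#' two-method intersection) and candidate-gene triage — with each stage
#' reading the previous stage's written outputs. Identical `config` produces
#' byte-identical scan/region/candidate files. A run manifest (configuration
#' snapshot, per-stage record counts and wall times) is written last.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of `c("simulate", "scan", "candidates")`,
#'   in pipeline order. When `"simulate"` is omitted, `config$io$depths`
#'   must point to an allele-depth file; when `"candidates"` is run without
#'   `"simulate"`, `config$io$gene_models` and `config$io$deg_table` must be
#'   set.
#' @return The run manifest (class `bsa_manifest`), invisibly. Files
#'   written: `depths.tsv`, `depths.vcf`, `pools.tsv`, `truth.tsv`,
#'   `gene_models.gff3`, `deg.tsv` (simulate); `scan.tsv`, `regions.bed`,
#'   `regions.tsv` (scan); `candidates.tsv` (candidates); `manifest.txt`,
#'   `config.txt`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "scan", "candidates")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  seed <- config$seed
  manifest <- list(version = as.character(utils::packageVersion("bsaqtl")),
                   seed = seed, config_hash = hash)
  times <- list()
  path <- function(f) file.path(out_dir, f)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "bsaqtl_stage_error")
    })
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  write_flat_config(.flatten_config(config), path("config.txt"))

  if ("simulate" %in% stages) {
    sim_out <- run_stage("simulate", function() {
      ds <- simulate_cross(config$sim)
      pools <- select_bulks(ds$phenotypes, config$sim$bulk_size)
      depths <- simulate_pool_depths(ds, pools)
      write_allele_depths_tsv(depths, path("depths.tsv"), seed, hash)
      write_allele_depths_vcf(depths, path("depths.vcf"), seed, hash)
      readr::write_lines(output_header(seed, hash), path("pools.tsv"))
      readr::write_tsv(pools, path("pools.tsv"), append = TRUE,
                       col_names = TRUE, progress = FALSE)
      qtl <- ds$snps[ds$snps$is_qtl, , drop = FALSE]
      truth <- tibble(qtl_snp_id = ds$qtl_snp_id, qtl_chrom = qtl$chrom,
                      qtl_pos = qtl$pos, qtl_pve = config$sim$qtl_pve)
      readr::write_lines(output_header(seed, hash), path("truth.tsv"))
      readr::write_tsv(truth, path("truth.tsv"), append = TRUE,
                       col_names = TRUE, progress = FALSE)

      genes <- simulate_gene_models(config$candidates$n_genes,
                                    chrom = config$sim$qtl_chrom,
                                    chrom_length_bp = config$sim$chrom_length_bp,
                                    seed = seed)
      # causal genes: those nearest the planted QTL respond to salt stress
      ord <- order(abs((genes$start + genes$end) / 2 - qtl$pos))
      causal <- genes$gene_id[head(ord, config$candidates$n_causal)]
      degs <- simulate_deg_table(genes, causal_genes = causal,
                                 causal_contrasts = config$candidates$contrasts,
                                 seed = seed)
      write_gene_models_gff3(genes, path("gene_models.gff3"), seed, hash)
      readr::write_lines(output_header(seed, hash), path("deg.tsv"))
      readr::write_tsv(degs[, c("gene_id", "contrast", "log2_ratio", "fdr")],
                       path("deg.tsv"), append = TRUE, col_names = TRUE,
                       progress = FALSE)
      list(n_lines = nrow(ds$genotypes), n_snps = nrow(ds$snps),
           n_genes = nrow(genes), causal = causal)
    })
    manifest$sim_lines <- sim_out$n_lines
    manifest$sim_snps <- sim_out$n_snps
    manifest$sim_genes <- sim_out$n_genes
  }

  regions_common <- NULL
  if ("scan" %in% stages) {
    scan_out <- run_stage("scan", function() {
      depth_path <- if ("simulate" %in% stages) path("depths.tsv") else
        config$io$depths
      if (is.null(depth_path) || !file.exists(depth_path))
        abort(sprintf("missing input for stage `scan`: allele depths (%s)",
                      depth_path %||% "io$depths not set"))
      depths <- read_allele_depths(
        depth_path, min_depth = config$filters$min_depth,
        max_depth_quantile = config$filters$max_depth_quantile)
      fc <- attr(depths, "filter_counts")

      scan <- compute_scan(depths, min_depth = config$filters$min_depth,
                           delta_convention = config$delta_convention)
      scan <- fit_scan(scan,
                       half_width_bp = config$smoothing$half_width_bp,
                       ed_power = config$smoothing$ed_power,
                       min_window_snps = config$smoothing$min_window_snps)
      bounds <- delta_null_bounds(scan$t_depth, scan$s_depth,
                                  bulk_size = config$sim$bulk_size,
                                  n_sims = config$thresholds$n_sims,
                                  seed = seed)
      scan$ci95 <- bounds$ci95
      scan$ci99 <- bounds$ci99
      thr <- if (identical(config$thresholds$ed_threshold_method, "null_sim")) {
        ed_null_threshold(scan, bulk_size = config$sim$bulk_size,
                          cm_per_mb = config$sim$cm_per_mb,
                          half_width_bp = config$smoothing$half_width_bp,
                          ed_power = config$smoothing$ed_power,
                          min_window_snps = config$smoothing$min_window_snps,
                          n_reps = config$thresholds$ed_null_reps,
                          prob = config$thresholds$ed_null_prob,
                          seed = seed)
      } else {
        ed_threshold(scan$fitted_ed,
                     multiplier = config$thresholds$ed_multiplier)
      }

      r_delta <- call_regions(scan, "delta",
                              ci_level = config$thresholds$delta_ci_level,
                              merge_gap_bp = config$thresholds$merge_gap_bp,
                              round_to_bp = config$thresholds$round_to_bp)
      r_ed <- call_regions(scan, "ed", threshold = thr,
                           merge_gap_bp = config$thresholds$merge_gap_bp)
      r_common <- intersect_region_sets(r_delta, r_ed)
      all_regions <- dplyr::bind_rows(r_delta, r_ed, r_common)

      write_scan_tsv(scan, path("scan.tsv"), seed, hash,
                     delta_convention = config$delta_convention)
      write_regions(all_regions, path("regions.bed"), path("regions.tsv"),
                    seed, hash)
      list(filter_counts = fc, ed_threshold = thr,
           n_delta = nrow(r_delta), n_ed = nrow(r_ed),
           common = r_common)
    })
    fc <- scan_out$filter_counts
    manifest$markers_read <- unname(fc["read"])
    manifest$markers_kept <- unname(fc["kept"])
    manifest$markers_filtered <- unname(fc["read"] - fc["kept"])
    manifest$ed_threshold <- scan_out$ed_threshold
    manifest$regions_delta <- scan_out$n_delta
    manifest$regions_ed <- scan_out$n_ed
    manifest$regions_common <- nrow(scan_out$common)
    regions_common <- scan_out$common
  }

  if ("candidates" %in% stages) {
    cand_out <- run_stage("candidates", function() {
      gene_path <- if ("simulate" %in% stages) path("gene_models.gff3") else
        config$io$gene_models
      deg_path <- if ("simulate" %in% stages) path("deg.tsv") else
        config$io$deg_table
      if (is.null(gene_path) || !file.exists(gene_path))
        abort(sprintf("missing input for stage `candidates`: gene models (%s)",
                      gene_path %||% "io$gene_models not set"))
      if (is.null(deg_path) || !file.exists(deg_path))
        abort(sprintf("missing input for stage `candidates`: DEG table (%s)",
                      deg_path %||% "io$deg_table not set"))
      if (is.null(regions_common)) {
        reg_path <- path("regions.tsv")
        if (!file.exists(reg_path))
          abort("missing input for stage `candidates`: regions (run `scan` first)")
        tab <- readr::read_tsv(reg_path, comment = "#",
                               show_col_types = FALSE, progress = FALSE)
        tab <- tab[tab$Method == "common", , drop = FALSE]
        regions_common <<- region_table(tab$Chromosome, tab$Start, tab$End,
                                        "common")
      }
      genes <- read_gene_models(gene_path)
      degs <- read_deg_table(deg_path)
      cands <- purrr::map_dfr(seq_len(nrow(regions_common)), function(i) {
        rg <- genes_in_region(genes, regions_common[i, ])
        out <- candidate_filter(rg, degs,
                                contrasts = config$candidates$contrasts)
        if (nrow(out) > 0) out$region <- sprintf(
          "%s:%d-%d", regions_common$chrom[i],
          as.integer(regions_common$start_bp[i]),
          as.integer(regions_common$end_bp[i]))
        out
      })
      if (nrow(cands) == 0)
        cands <- tibble(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        min_fdr = numeric(),
                        n_significant_contrasts = integer(),
                        region = character())
      readr::write_lines(output_header(seed, hash), path("candidates.tsv"))
      readr::write_tsv(cands, path("candidates.tsv"), append = TRUE,
                       col_names = TRUE, progress = FALSE)
      nrow(cands)
    })
    manifest$candidates_n <- cand_out
  }

  manifest$stage_seconds <- unlist(times)
  out <- structure(manifest, class = "bsa_manifest")
  write_flat_config(unclass(out), path("manifest.txt"))
  invisible(out)
}

.flatten_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$io <- NULL
  flat <- unlist(cfg)
  as.list(flat)
}

#' @export
print.bsa_manifest <- function(x, ...) {
  cat("<bsa_manifest>\n")
  flat <- unlist(unclass(x))
  cat(sprintf("  %s: %s\n", names(flat), as.character(flat)), sep = "")
  invisible(x)
}
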