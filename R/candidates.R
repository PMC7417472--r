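#' Classify differential expression calls
#'
#' A gene is significantly differentially expressed in a contrast when
#' `FDR < 0.05` (equivalently `-log10(FDR) > 1.3`); the direction is `"up"`
#' for a positive log2 ratio and `"down"` for a negative one. A significant
#' call with a log2 ratio of exactly 0 has no direction and is classified
#' `"ns"` with a warning.
#'
#' @param log2_ratio Log2 expression ratio(s).
#' @param fdr False-discovery-rate adjusted p-value(s), in `[0, 1]`.
#' @param fdr_cutoff Significance cutoff (default 0.05, strict `<`).
#' @param min_abs_log2 Optional absolute log2-ratio requirement on top of
#'   the FDR rule (default 0 = off).
#' @return Tibble with `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"ns"`).
#' @export
#' @examples
#' classify_deg(-1.2, 0.04)   # significant, down
#' classify_deg(2.0, 0.05)    # not significant: the cutoff is strict
classify_deg <- function(log2_ratio, fdr, fdr_cutoff = 0.05, min_abs_log2 = 0) {
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE))
    abort("fdr values must lie in [0, 1]")
  n <- max(length(log2_ratio), length(fdr))
  log2_ratio <- rep_len(log2_ratio, n)
  fdr <- rep_len(fdr, n)
  significant <- !is.na(fdr) & fdr < fdr_cutoff &
    (min_abs_log2 <= 0 | abs(log2_ratio) >= min_abs_log2)
  zero_sig <- significant & log2_ratio == 0
  if (any(zero_sig)) {
    warn(sprintf("%d significant record(s) with log2 ratio 0: classified ns",
                 sum(zero_sig)))
    significant[zero_sig] <- FALSE
  }
  direction <- rep("ns", n)
  direction[significant & log2_ratio > 0] <- "up"
  direction[significant & log2_ratio < 0] <- "down"
  tibble(significant = significant, direction = direction)
}

#' Venn partition of labelled gene sets
#'
#' Partitions the union of `k` labelled sets into the `2^k - 1` disjoint
#' membership subgroups of a Venn diagram (15 subgroups for four sets) and
#' reports each subgroup's count and percentage of the union (rounded to
#' 2 decimals). Counts always sum to the union size.
#'
#' @param sets Named list of character vectors (at least 2 sets).
#' @return Tibble with one row per membership pattern: one logical column
#'   per set, `pattern` (set names joined by `&`), `count`, `percent`.
#' @export
#' @examples
#' venn_partition(list(A = c("g1", "g2"), B = c("g2", "g3")))
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)

  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)

  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, , drop = FALSE]
  colnames(patterns) <- names(sets)
  key_of <- function(m) apply(m, 1, function(r) paste(as.integer(r), collapse = ""))

  counts <- if (length(universe) > 0) table(key_of(membership)) else table(character())
  keys <- key_of(patterns)
  n_union <- length(universe)
  count <- as.integer(counts[keys])
  count[is.na(count)] <- 0L

  out <- as_tibble(patterns)
  out$pattern <- apply(patterns, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  out$count <- count
  out$percent <- if (n_union > 0) round(100 * count / n_union, 2) else 0
  out
}

#' Genes overlapping a genomic region
#'
#' Returns the gene models whose span overlaps the region by at least 1 bp
#' (`mode = "any"`, the default) or that lie entirely within it
#' (`mode = "within"`), sorted by start position.
#'
#' @param genes Gene-model tibble: `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param region A one-row region (tibble or list) with `chrom`, `start_bp`,
#'   `end_bp`.
#' @param mode `"any"` (default) or `"within"`.
#' @return The overlapping subset of `genes`, sorted by `start`.
#' @export
genes_in_region <- function(genes, region, mode = c("any", "within")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(region)))
  hit <- genes$chrom == region$chrom &
    if (mode == "any") {
      genes$start <= region$end_bp & genes$end >= region$start_bp
    } else {
      genes$start >= region$start_bp & genes$end <= region$end_bp
    }
  arrange(as_tibble(genes)[hit, , drop = FALSE], .data$start)
}

#' Filter region genes against the DEG table: the candidate list
#'
#' The candidate genes of a mapped region are those differentially
#' expressed, in at least one of the designated contrasts, among the genes
#' the region contains. By default the designated contrasts are the two
#' within-variety salt-response comparisons (`IRvsTIR`, `WGvsTWG`).
#' Candidates are ranked by their minimum FDR across the designated
#' contrasts; per-contrast directions are reported alongside.
#'
#' @param region_genes Gene models inside the region (from
#'   [genes_in_region()]).
#' @param degs DEG tibble: `gene_id`, `contrast`, `log2_ratio`, `fdr` (and
#'   optionally precomputed `significant`/`direction`; recomputed if absent).
#' @param contrasts Designated contrast labels.
#' @return Tibble of candidates sorted by `min_fdr`: `gene_id`, `chrom`,
#'   `start`, `end`, `min_fdr`, `n_significant_contrasts`, then one
#'   `dir_<contrast>` column per designated contrast.
#' @export
candidate_filter <- function(region_genes, degs,
                             contrasts = c("IRvsTIR", "WGvsTWG")) {
  stopifnot(all(c("gene_id", "contrast", "log2_ratio", "fdr") %in% names(degs)))
  known <- unique(degs$contrast)
  if (!all(contrasts %in% known) && nrow(degs) > 0)
    abort(sprintf("designated contrast(s) not present in the DEG table: %s",
                  paste(setdiff(contrasts, known), collapse = ", ")))
  if (!all(c("significant", "direction") %in% names(degs)))
    degs <- dplyr::bind_cols(degs[c("gene_id", "contrast", "log2_ratio", "fdr")],
                             classify_deg(degs$log2_ratio, degs$fdr))

  orphan <- setdiff(unique(degs$gene_id), region_genes$gene_id)
  # DEG genes outside the region/annotation are simply not candidates; only
  # note them at scale
  if (length(orphan) > 0)
    inform(sprintf("%d DEG gene id(s) not in the region gene list (skipped)",
                   length(orphan)))

  sub <- degs |>
    filter(.data$contrast %in% contrasts,
           .data$gene_id %in% region_genes$gene_id)
  hits <- sub |>
    group_by(.data$gene_id) |>
    summarise(min_fdr = if (any(.data$significant))
                min(.data$fdr[.data$significant]) else Inf,
              n_significant_contrasts = sum(.data$significant),
              .groups = "drop") |>
    filter(.data$n_significant_contrasts > 0)
  if (nrow(hits) == 0)
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), min_fdr = numeric(),
                  n_significant_contrasts = integer()))

  dirs <- sub |>
    filter(.data$gene_id %in% hits$gene_id) |>
    select(all_of(c("gene_id", "contrast", "direction"))) |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "direction",
                       names_prefix = "dir_")

  hits |>
    inner_join(region_genes[, c("gene_id", "chrom", "start", "end")],
               by = "gene_id") |>
    left_join(dirs, by = "gene_id") |>
    select(all_of(c("gene_id", "chrom", "start", "end", "min_fdr",
                    "n_significant_contrasts")), dplyr::starts_with("dir_")) |>
    arrange(.data$min_fdr, .data$gene_id)
}

#' Parental variants in or near candidate genes
#'
#' Annotates candidate genes with parental-variant records (e.g. SNPs or
#' indels segregating between the parents) that fall within the gene body
#' or a promoter window upstream of it. "Upstream" respects strand: for a
#' `+` gene the window precedes `start`, for a `-` gene it follows `end`;
#' strandless genes get the window on both sides.
#'
#' @param variants Tibble of variant records with `chrom`, `pos` (1-based)
#'   and any further columns (carried through).
#' @param genes Gene-model tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param promoter_bp Upstream window size in bp (default 2000).
#' @return The variant records overlapping any gene's window, one row per
#'   (variant, gene) pair, with `gene_id` and a `location` column
#'   (`"gene_body"` or `"promoter"`) added; sorted by `(chrom, pos)`.
#' @export
variants_near_genes <- function(variants, genes, promoter_bp = 2000) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    win_start <- g$start - if (g$strand %in% c("+", ".")) promoter_bp else 0
    win_end <- g$end + if (g$strand %in% c("-", ".")) promoter_bp else 0
    hit <- variants$chrom == g$chrom & variants$pos >= max(1, win_start) &
      variants$pos <= win_end
    if (!any(hit)) return(NULL)
    v <- as_tibble(variants)[hit, , drop = FALSE]
    v$gene_id <- g$gene_id
    v$location <- ifelse(v$pos >= g$start & v$pos <= g$end,
                         "gene_body", "promoter")
    v
  })
  if (nrow(out) == 0)
    return(dplyr::bind_cols(as_tibble(variants)[0, ],
                            tibble(gene_id = character(),
                                   location = character())))
  arrange(out, .data$chrom, .data$pos)
}

#' Relative expression by the 2^-ddCt method
#'
#' Quantitative RT-PCR relative expression: for each condition the target
#' gene's Ct is normalised against the internal-control gene
#' (`dCt = ct_target - ct_reference`), the treatment dCt is referenced to
#' the control dCt (`ddCt = dCt_treatment - dCt_control`), and the fold
#' change is `2^-ddCt`.
#'
#' @param assay_treatment,assay_control Lists or one-row data frames with
#'   numeric `ct_target` and `ct_reference` (cycle-threshold values > 0).
#' @return The fold change `2^-ddCt`.
#' @export
#' @examples
#' ddct_relative_expression(list(ct_target = 20, ct_reference = 18),
#'                          list(ct_target = 24, ct_reference = 20))  # 4
ddct_relative_expression <- function(assay_treatment, assay_control) {
  get_ct <- function(assay, which) {
    val <- assay[[which]]
    if (is.null(val) || anyNA(val))
      abort(sprintf("missing %s in assay", which))
    if (any(val <= 0)) abort("Ct values must be > 0")
    val
  }
  dct_trt <- get_ct(assay_treatment, "ct_target") -
    get_ct(assay_treatment, "ct_reference")
  dct_ctl <- get_ct(assay_control, "ct_target") -
    get_ct(assay_control, "ct_reference")
  2^(-(dct_trt - dct_ctl))
}

#' One-way ANOVA of a marker genotype against a trait
#'
#' Tests whether trait means differ among the three genotype classes of a
#' single marker (female-parent homozygote, heterozygote, male-parent
#' homozygote) with a fixed-effects one-way ANOVA, as used to validate a
#' KASP marker against the mapping trait.
#'
#' @param genotype Per-line genotype class labels (e.g. `"AA"`, `"Aa"`,
#'   `"aa"`); at least 2 classes with at least 2 observations each.
#' @param values Per-line trait values.
#' @return An object of class `genotype_anova` with [tidy()] (per-class
#'   summaries) and [glance()] (F statistic, degrees of freedom, p-value)
#'   methods.
#' @export
#' @examples
#' fit <- genotype_anova(rep(c("AA", "Aa", "aa"), each = 5),
#'                       c(rnorm(5, 1), rnorm(5, 2), rnorm(5, 3)))
#' glance(fit)
genotype_anova <- function(genotype, values) {
  stopifnot(length(genotype) == length(values))
  keep <- !is.na(genotype) & !is.na(values)
  genotype <- factor(genotype[keep])
  values <- values[keep]
  tab <- table(genotype)
  if (length(tab) < 2)
    abort("genotype ANOVA needs at least 2 genotype classes (got 1)")
  if (sum(tab >= 2) < 2)
    abort("genotype ANOVA needs at least 2 classes with >= 2 observations")

  fit <- lm(values ~ genotype)
  # perfect within-class fits make anova.lm warn; the F/p values are still
  # the right degenerate limits
  an <- suppressWarnings(anova(fit))
  f_stat <- an$`F value`[1]
  p_val <- an$`Pr(>F)`[1]
  if (stats::var(values) == 0) {
    # degenerate: no variation at all, nothing to explain
    f_stat <- 0
    p_val <- 1
  }
  means <- tibble(class = levels(genotype),
                  n = as.integer(tab),
                  mean = as.numeric(tapply(values, genotype, mean)),
                  sd = as.numeric(tapply(values, genotype, sd)))
  structure(
    list(group_means = means,
         f_statistic = f_stat,
         df_between = an$Df[1], df_within = an$Df[2],
         p_value = p_val,
         n = length(values), model = fit),
    class = "genotype_anova"
  )
}

#' @export
print.genotype_anova <- function(x, ...) {
  cat("<genotype_anova>\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g, n = %d\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value, x$n))
  print(x$group_means)
  invisible(x)
}

#' @rdname genotype_anova
#' @param x,object A `genotype_anova` object.
#' @param ... Unused.
#' @export
tidy.genotype_anova <- function(x, ...) {
  x$group_means
}

#' @rdname genotype_anova
#' @export
glance.genotype_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_between = x$df_between,
         df_within = x$df_within, p_value = x$p_value, n = x$n)
}
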