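test_that("DEG classification follows the strict FDR rule with directions", {
  expect_identical(classify_deg(-1.2, 0.04),
                   tibble::tibble(significant = TRUE, direction = "down"))
  expect_identical(classify_deg(2, 0.05)$significant, FALSE)  # strict cutoff
  expect_identical(classify_deg(3, 0.5)$direction, "ns")
  expect_warning(zero <- classify_deg(0, 0.01), "log2 ratio 0")
  expect_identical(zero$direction, "ns")
  expect_error(classify_deg(1, 1.2), "\\[0, 1\\]")
  # -log10(FDR) > 1.3 is the same rule as FDR < 0.05 at table precision
  fdr <- c(0.049, 0.05, 0.051)
  expect_identical(classify_deg(1, fdr)$significant, -log10(fdr) > -log10(0.05))
})

test_that("the four-set Venn partition has 15 subgroups summing to the union", {
  sets <- list(A = paste0("g", 1:50), B = paste0("g", 26:80),
               C = paste0("g", 60:90), D = paste0("g", c(1:5, 85:100)))
  vp <- venn_partition(sets)
  expect_identical(nrow(vp), 15L)
  expect_identical(sum(vp$count), length(unique(unlist(sets))))

  # identical sets collapse onto the all-four subgroup
  same <- venn_partition(list(A = letters, B = letters, C = letters,
                              D = letters))
  expect_identical(same$count[same$pattern == "A&B&C&D"], 26L)
  expect_identical(sum(same$count), 26L)
})

test_that("Venn counts match the per-id membership oracle", {
  set.seed(41)
  universe <- paste0("id", 1:200)
  sets <- list(W = sample(universe, 50), X = sample(universe, 50),
               Y = sample(universe, 50), Z = sample(universe, 50))
  vp <- venn_partition(sets)
  for (row in sample(nrow(vp), 6)) {
    members <- names(sets)[unlist(vp[row, names(sets)])]
    expect_identical(vp$count[row], oracle_venn_count(sets, members))
  }
  expect_equal(vp$percent,
               round(100 * vp$count / length(unique(unlist(sets))), 2))
})

test_that("gene-region overlap uses the any-overlap rule", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(100, 401), end = c(200, 500),
                          strand = "+")
  region <- region_table("chr1", 150, 400, "common")
  hit <- genes_in_region(genes, region)
  expect_identical(hit$gene_id, "a")       # partial overlap in, adjacent out
  expect_identical(nrow(genes_in_region(genes, region, mode = "within")), 0L)

  set.seed(42)
  tiled <- simulate_gene_models(50, chrom_length_bp = 1e6,
                                gene_length_bp = 8000, seed = 42)
  for (i in 1:5) {
    s <- sample(1:9e5, 1)
    region <- region_table("chr1", s, s + 5e4, "common")
    got <- genes_in_region(tiled, region)
    expect_identical(sort(got$gene_id),
                     oracle_genes_overlap(tiled, "chr1", s, s + 5e4))
  }
})

test_that("candidate filtering returns exactly the planted responsive genes", {
  genes <- simulate_gene_models(27, chrom_length_bp = 4.17e6, seed = 7)
  causal <- genes$gene_id[c(3, 8, 12, 19, 25)]
  degs <- simulate_deg_table(genes, causal_genes = causal, seed = 7)
  region <- region_table("chr1", 1, 4.17e6, "common")
  rg <- genes_in_region(genes, region)
  # a null FDR can dip under 0.05 by chance; restrict to the planted truth
  degs$fdr[!(degs$gene_id %in% causal &
               degs$contrast %in% c("IRvsTIR", "WGvsTWG"))] <- 0.5
  degs$significant <- NULL; degs$direction <- NULL
  out <- candidate_filter(rg, degs)
  expect_setequal(out$gene_id, causal)
  expect_true(all(out$dir_IRvsTIR == "down"))
  expect_identical(out$gene_id, out$gene_id[order(out$min_fdr)])
  # candidates are always a subset of the region's genes
  expect_true(all(out$gene_id %in% rg$gene_id))
})

test_that("non-designated contrasts and empty inputs yield no candidates", {
  genes <- simulate_gene_models(10, seed = 8)
  degs <- tibble::tibble(gene_id = genes$gene_id[1],
                         contrast = "WGvsIR", log2_ratio = -3, fdr = 1e-6)
  region <- region_table("chr1", 1, 30e6, "common")
  rg <- genes_in_region(genes, region)
  expect_error(candidate_filter(rg, degs), "not present")
  degs4 <- simulate_deg_table(genes, seed = 8)
  degs4$fdr <- 0.9
  degs4$significant <- NULL; degs4$direction <- NULL
  # significant only in a non-designated contrast: excluded
  degs4$fdr[degs4$gene_id == genes$gene_id[2] &
              degs4$contrast == "WGvsIR"] <- 1e-5
  expect_identical(nrow(candidate_filter(rg, degs4)), 0L)
})

test_that("2^-ddCt relative expression matches hand calculations", {
  mk <- function(t, r) list(ct_target = t, ct_reference = r)
  expect_identical(ddct_relative_expression(mk(22, 18), mk(24, 20)), 1)
  expect_identical(ddct_relative_expression(mk(23, 18), mk(24, 20)), 0.5)
  expect_identical(ddct_relative_expression(mk(20, 18), mk(24, 20)), 4)
  # swapping conditions returns the reciprocal
  a <- mk(21.7, 18.2); b <- mk(24.1, 19.9)
  expect_equal(ddct_relative_expression(a, b),
               1 / ddct_relative_expression(b, a))
  expect_error(ddct_relative_expression(list(ct_target = 20), b), "missing")
  expect_error(ddct_relative_expression(mk(-1, 5), b), "> 0")
})

test_that("marker-genotype ANOVA separates classes and degrades gracefully", {
  fit <- genotype_anova(rep(c("AA", "Aa", "aa"), each = 2),
                        c(1, 1, 2, 2, 3, 3))
  expect_lt(fit$p_value, 0.01)
  td <- tidy(fit)
  expect_identical(td$mean[match(c("AA", "Aa", "aa"), td$class)], c(1, 2, 3))

  flat <- genotype_anova(rep(c("AA", "aa"), each = 3), rep(5, 6))
  expect_identical(flat$f_statistic, 0)
  expect_identical(flat$p_value, 1)

  expect_error(genotype_anova(rep("AA", 6), rnorm(6)), "2 genotype classes")
  g <- glance(fit)
  expect_identical(g$df_between, 2L)
  expect_identical(g$n, 6L)
})

test_that("a PVE-0.25 marker is detected by ANOVA in a 199-line validation set", {
  hits <- vapply(1:20, function(s) {
    ds <- simulate_cross(sim_config(n_lines = 199, bulk_size = 40,
                                    n_snps_per_chrom = 10, qtl_pve = 0.25,
                                    seed = s))
    g <- c("aa", "Aa", "AA")[ds$genotypes[, ds$qtl_snp_id] + 1L]
    genotype_anova(g, ds$phenotypes$value)$p_value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("parental variants annotate gene bodies and strand-aware promoters", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          start = c(10000, 50000), end = c(12000, 52000),
                          strand = c("+", "-"))
  variants <- tibble::tibble(chrom = "chr1",
                             pos = c(9500, 11000, 13000, 52500, 49500),
                             ref = "A", alt = "AT")
  out <- variants_near_genes(variants, genes, promoter_bp = 2000)
  # + gene: window [8000, 12000]; - gene: window [50000, 54000]
  expect_identical(out$pos, c(9500, 11000, 52500))
  expect_identical(out$location, c("promoter", "gene_body", "promoter"))
  expect_identical(out$gene_id, c("gp", "gp", "gm"))
  none <- variants_near_genes(variants[3, ], genes[1, ])
  expect_identical(nrow(none), 0L)
  expect_true(all(c("gene_id", "location") %in% names(none)))
})
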