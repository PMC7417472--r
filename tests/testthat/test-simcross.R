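test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_lines = 0), "n_lines")
  expect_error(sim_config(n_lines = 50, bulk_size = 40), "bulk_size")
  expect_error(sim_config(qtl_pve = 1), "qtl_pve")
  expect_error(sim_config(qtl_pve = -0.1), "qtl_pve")
  expect_error(sim_config(qtl_pos_bp = 40e6, chrom_length_bp = 30e6), "qtl_pos_bp")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(qtl_chrom = "chr9", n_chrom = 2), "qtl_chrom")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_lines = 80, bulk_size = 10, n_snps_per_chrom = 60,
                    seed = 11)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  pa <- select_bulks(a$phenotypes, 10)
  da <- suppressMessages(simulate_pool_depths(a, pa))
  db <- suppressMessages(simulate_pool_depths(b, select_bulks(b$phenotypes, 10)))
  expect_identical(da, db)
})

test_that("a null QTL leaves phenotype and genotype uncorrelated", {
  cfg <- sim_config(n_lines = 2000, bulk_size = 40, n_snps_per_chrom = 30,
                    qtl_pve = 0, seed = 5)
  ds <- simulate_cross(cfg)
  gq <- ds$genotypes[, ds$qtl_snp_id]
  expect_lt(abs(cor(ds$phenotypes$value, gq)), 0.07)
})

test_that("the additive QTL explains close to the requested variance fraction", {
  r2 <- vapply(1:100, function(s) {
    ds <- simulate_cross(sim_config(n_lines = 983, bulk_size = 40,
                                    n_snps_per_chrom = 40, qtl_pve = 0.249,
                                    seed = s))
    cor(ds$phenotypes$value, ds$genotypes[, ds$qtl_snp_id])^2
  }, numeric(1))
  expect_true(all(r2 > 0.15 & r2 < 0.35))
  expect_lt(abs(mean(r2) - 0.249), 0.02)
})

test_that("marker genotypes segregate 1:2:1", {
  ds <- simulate_cross(sim_config(n_lines = 983, bulk_size = 40,
                                  n_snps_per_chrom = 200, seed = 3))
  pvals <- apply(ds$genotypes, 2, function(g) {
    obs <- tabulate(g + 1L, nbins = 3)
    suppressWarnings(chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value)
  })
  expect_gt(min(pvals), 0.001)
})

test_that("extreme bulks take the phenotypic tails, disjointly", {
  ph <- tibble::tibble(line_id = paste0("L", 1:6), value = c(1, 2, 3, 4, 5, 6))
  out <- select_bulks(ph, 2)
  expect_setequal(out$line_id[out$pool == "T"], c("L5", "L6"))
  expect_setequal(out$line_id[out$pool == "S"], c("L1", "L2"))

  sim <- tiny_experiment(seed = 9, n_lines = 983, bulk_size = 40, n_snps = 20)
  pools <- sim$pools
  expect_identical(sum(pools$pool == "T"), 40L)
  expect_identical(sum(pools$pool == "S"), 40L)
  expect_length(intersect(pools$line_id[pools$pool == "T"],
                          pools$line_id[pools$pool == "S"]), 0)
  expect_gte(min(pools$value[pools$pool == "T"]),
             max(pools$value[pools$pool == "S"]))
})

test_that("boundary ties are resolved by line id with a warning", {
  ph <- tibble::tibble(line_id = paste0("L", 1:6), value = rep(1, 6))
  w <- testthat::capture_warnings(out <- select_bulks(ph, 2))
  expect_length(w, 2)  # both selection boundaries sit inside the tie
  expect_match(w, "tie", all = TRUE)
  expect_setequal(out$line_id[out$pool == "S"], c("L1", "L2"))
  expect_setequal(out$line_id[out$pool == "T"], c("L5", "L6"))
  expect_error(select_bulks(ph[1:3, ], 2), "cannot form")
  expect_error(select_bulks(tibble::tibble(line_id = c("a", "b"),
                                           value = c(NA, 1)), 1),
               "missing")
})

test_that("pool depths follow the binomial read-sampling model", {
  # pool fixed for alt (f = 1) and for ref (f = 0)
  g <- matrix(2L, nrow = 20, ncol = 50)
  g[11:20, ] <- 0L
  ds <- manual_dataset(g, mean_depth = 30, depth_model = "fixed")
  pools <- tibble::tibble(line_id = sprintf("L%04d", 1:20),
                          pool = rep(c("T", "S"), each = 10))
  d <- simulate_pool_depths(ds, pools)
  expect_true(all(d$t_alt == 30 & d$t_ref == 0))   # f = 1
  expect_true(all(d$s_alt == 0 & d$s_ref == 30))   # f = 0

  # all-heterozygous pools: f = 0.5, law of large numbers over 10,000 SNPs
  g <- matrix(1L, nrow = 20, ncol = 10000)
  ds <- manual_dataset(g, mean_depth = 30, depth_model = "fixed")
  d <- simulate_pool_depths(ds, pools)
  expect_lt(abs(mean(d$t_alt / 30) - 0.5), 0.01)
})

test_that("pooled allele-frequency divergence is enriched at the causal marker", {
  wins <- vapply(1:20, function(s) {
    sim <- tiny_experiment(seed = s, n_lines = 200, bulk_size = 40,
                           n_snps = 30, n_chrom = 2, qtl_pve = 0.25)
    qtl <- sim$ds$snps$is_qtl
    unlinked <- sim$ds$snps$chrom != sim$cfg$qtl_chrom
    div <- abs(sim$depths$true_f_t - sim$depths$true_f_s)
    div[qtl] > mean(div[unlinked])
  }, logical(1))
  # paired sign test: divergence at the QTL beats the unlinked mean
  expect_lt(binom.test(sum(wins), 20, 0.5, alternative = "greater")$p.value,
            0.01)
})
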