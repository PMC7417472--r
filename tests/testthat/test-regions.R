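test_that("region sizes follow the (end - start)/1e6 convention", {
  r <- region_table("chr7", 20160000, 24330000, "common")
  expect_identical(r$size_mb, 4.17)
  expect_error(region_table("chr1", 10, 5, "ed"), "start_bp")
  expect_error(region_table("chr1", 0, 5, "ed"), "1-based")
})

test_that("region calling finds runs, merges small gaps, rounds delta bounds", {
  pos <- seq(1e5, 3e6, by = 1e5)  # 30 SNPs
  scan <- tibble::tibble(
    chrom = "chr1", pos = pos,
    fitted_delta = 0, ci95 = 0.2, ci99 = 0.3,
    fitted_ed = 0)
  scan$fitted_delta[5:8] <- 0.5
  scan$fitted_ed[12:15] <- 1

  rd <- call_regions(scan, "delta")
  expect_identical(nrow(rd), 1L)
  # outward rounding to the 10-kb grid
  expect_identical(rd$start_bp, floor(pos[5] / 1e4) * 1e4)
  expect_identical(rd$end_bp, ceiling(pos[8] / 1e4) * 1e4)
  expect_identical(rd$method, "delta_snp_index")

  re <- call_regions(scan, "ed", threshold = 0.5)
  expect_identical(nrow(re), 1L)
  expect_identical(re$start_bp, pos[12])  # ED keeps raw SNP positions
  expect_identical(re$end_bp, pos[15])

  expect_identical(nrow(call_regions(scan, "ed", threshold = 2)), 0L)
  expect_error(call_regions(scan, "ed"), "threshold")
})

test_that("runs separated by small gaps merge; chromosomes never do", {
  scan <- tibble::tibble(
    chrom = "chr1",
    pos = c(1e6, 1.1e6, 1.5e6, 1.6e6, 3e6, 3.1e6),
    fitted_ed = c(1, 1, 0, 0, 1, 1), fitted_delta = 0, ci95 = 1)
  # gap run1-end (1.1 Mb) to run2-start (3 Mb) = 1.9 Mb > 0.5 Mb: two regions
  r <- call_regions(scan, "ed", threshold = 0.5)
  expect_identical(nrow(r), 2L)
  # raising merge_gap_bp to 2 Mb merges them
  r2 <- call_regions(scan, "ed", threshold = 0.5, merge_gap_bp = 2e6)
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$start_bp, 1e6)
  expect_identical(r2$end_bp, 3.1e6)

  scan2 <- scan
  scan2$chrom <- rep(c("chr1", "chr2"), each = 3)
  scan2$fitted_ed <- 1
  r3 <- call_regions(scan2, "ed", threshold = 0.5, merge_gap_bp = 1e9)
  expect_identical(nrow(r3), 2L)
  expect_setequal(r3$chrom, c("chr1", "chr2"))
})

test_that("region calling matches the brute-force run oracle", {
  set.seed(27)
  for (rep in 1:10) {
    n <- 200
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    pos <- as.numeric(unlist(tapply(sample(1:5e6, n), chrom, sort)))
    fitted <- ifelse(runif(n) < 0.3, 1, 0)
    scan <- tibble::tibble(chrom = chrom, pos = pos, fitted_ed = fitted)
    got <- call_regions(scan, "ed", threshold = 0.5, merge_gap_bp = 2e5)
    want <- oracle_call_runs(chrom, pos, fitted > 0.5, merge_gap = 2e5)
    expect_equal(got[, c("chrom", "start_bp", "end_bp")], want,
                 ignore_attr = TRUE)
  }
})

test_that("two-method intersection reproduces the worked QTL-seq example", {
  delta_regions <- region_table(
    c("chr1", "chr1", "chr7"),
    c(4590000, 7800000, 20160000),
    c(7270000, 10720000, 24330000), "delta_snp_index")
  ed_regions <- region_table(
    c("chr7", "chr7"), c(6942377, 12547138), c(12109211, 26674659), "ed")
  expect_identical(delta_regions$size_mb, c(2.68, 2.92, 4.17))
  expect_identical(ed_regions$size_mb, c(5.17, 14.13))

  common <- intersect_region_sets(delta_regions, ed_regions)
  expect_identical(nrow(common), 1L)
  expect_identical(common$chrom, "chr7")
  expect_identical(common$start_bp, 20160000)
  expect_identical(common$end_bp, 24330000)
  expect_identical(common$size_mb, 4.17)
  expect_identical(common$method, "common")
})

test_that("intersection is empty on disjoint sets and idempotent on identical ones", {
  a <- region_table("chr1", 100, 200, "delta_snp_index")
  b <- region_table("chr1", 300, 400, "ed")
  expect_identical(nrow(intersect_region_sets(a, b)), 0L)
  same <- intersect_region_sets(a, a)
  expect_identical(same$start_bp, 100)
  expect_identical(same$end_bp, 200)
  expect_identical(nrow(intersect_region_sets(a, a[0, ])), 0L)
})

test_that("intersection matches a brute-force positional sweep", {
  set.seed(28)
  for (rep in 1:10) {
    # disjoint, well-separated intervals per set (the shape region calling
    # produces), so pairwise intersection and a positional sweep agree
    mk <- function(n) {
      pts <- sort(sample(seq(1, 999, by = 3), 2 * n))
      region_table(sample(c("chr1", "chr2"), n, TRUE),
                   pts[seq(1, 2 * n, by = 2)],
                   pts[seq(2, 2 * n, by = 2)], "x")
    }
    a <- mk(4); b <- mk(3)
    got <- intersect_region_sets(a, b)[, c("chrom", "start_bp", "end_bp")]
    want <- oracle_intersect_grid(a, b)
    expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("coordinate dialect conversion is exact and reversible", {
  r <- region_table("chr7", 20160000, 24330000, "common")
  bed <- convert_coordinates(r, "bed_0based_halfopen")
  expect_identical(bed$start_bp, 20159999)
  expect_identical(bed$end_bp, 24330000)
  # length preserved: bed length = inclusive length
  expect_identical(bed$end_bp - bed$start_bp, r$end_bp - r$start_bp + 1)
  back <- convert_coordinates(bed, "internal_1based_inclusive")
  expect_identical(back$start_bp, r$start_bp)
  expect_identical(back$end_bp, r$end_bp)
})
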