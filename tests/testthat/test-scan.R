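test_that("SNP-index is the alt-read fraction, filtered below min depth", {
  expect_identical(snp_index(10, 10), 0.5)
  expect_identical(snp_index(0, 20), 1)
  expect_equal(snp_index(21, 9), 0.3)
  expect_true(is.na(snp_index(2, 1)))           # depth 3 < 7
  expect_identical(snp_index(2, 1, min_depth = 3), 1 / 3)
  expect_error(snp_index(-1, 5), "non-negative")
})

test_that("delta SNP-index subtracts the T-pool index from the S-pool index", {
  expect_equal(delta_snp_index(0.8, 0.3), -0.5)
  expect_identical(delta_snp_index(0.4, 0.4), 0)
  expect_identical(delta_snp_index(0, 1), 1)
  expect_equal(delta_snp_index(0.8, 0.3, convention = "t_minus_s"), 0.5)
})

test_that("ED matches hand evaluation on closed-form inputs", {
  f <- function(a, c, g, t) c(a, c, g, t)
  expect_identical(euclidean_distance(f(0.4, 0.6, 0, 0), f(0.4, 0.6, 0, 0)), 0)
  expect_equal(euclidean_distance(f(1, 0, 0, 0), f(0, 1, 0, 0)), sqrt(2),
               tolerance = 1e-9)
  expect_equal(euclidean_distance(f(0.7, 0.3, 0, 0), f(0.4, 0.6, 0, 0)),
               sqrt(0.18), tolerance = 1e-9)
  expect_error(euclidean_distance(f(0.5, 0.4, 0, 0), f(1, 0, 0, 0)), "sum to 1")
})

test_that("ED is symmetric and satisfies the triangle inequality", {
  set.seed(17)
  for (i in 1:25) {
    p <- as.numeric(rmultinom(1, 100, runif(4))) / 100
    q <- as.numeric(rmultinom(1, 100, runif(4))) / 100
    r <- as.numeric(rmultinom(1, 100, runif(4))) / 100
    expect_identical(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("delta and ED vanish together at biallelic markers", {
  set.seed(18)
  scan <- compute_scan(tibble::tibble(
    chrom = "chr1", pos = 1:60 * 1000, ref = "A", alt = "G",
    t_ref = rbinom(60, 30, 0.5), t_alt = rbinom(60, 30, 0.5) + 5,
    s_ref = rbinom(60, 30, 0.5), s_alt = rbinom(60, 30, 0.5) + 5),
    min_depth = 1)
  expect_identical(scan$ed == 0,
                   scan$snp_index_t == scan$snp_index_s)
  expect_identical(scan$ed == 0, scan$delta_snp_index == 0)
  # dual route: the biallelic closed form equals the 4-base-vector formula
  ed_vec <- vapply(seq_len(nrow(scan)), function(i) {
    euclidean_distance(
      base_frequencies("A", "G", scan$t_depth[i] - scan$t_depth[i] * scan$snp_index_t[i],
                       scan$t_depth[i] * scan$snp_index_t[i]),
      base_frequencies("A", "G", scan$s_depth[i] - scan$s_depth[i] * scan$snp_index_s[i],
                       scan$s_depth[i] * scan$snp_index_s[i]))
  }, numeric(1))
  expect_equal(scan$ed, ed_vec, tolerance = 1e-12)
})

test_that("the tricube kernel preserves constants and localizes spikes", {
  pos <- seq(1e4, 1e7, length.out = 500)
  scan <- tibble::tibble(chrom = "chr1", pos = pos, ed = 0.3,
                         delta_snp_index = 0.1)
  fit <- fit_scan(scan, half_width_bp = 1e6, ed_power = 4, min_window_snps = 1)
  expect_equal(fit$fitted_ed, rep(0.3^4, 500), tolerance = 1e-12)
  expect_equal(fit$fitted_delta, rep(0.1, 500), tolerance = 1e-12)

  # one spike among 1000: peak sits at the spike, attenuated below raw^p
  pos <- seq(1e4, 2e7, length.out = 1000)
  y <- rep(0, 1000); y[400] <- 1
  sp <- fit_scan(tibble::tibble(chrom = "chr1", pos = pos, ed = y),
                 statistic = "ed", half_width_bp = 1e6, min_window_snps = 1)
  expect_identical(which.max(sp$fitted_ed), 400L)
  expect_lt(max(sp$fitted_ed), 1)
  oracle <- oracle_tricube(pos, y^4, 1e6)
  expect_equal(sp$fitted_ed, oracle, tolerance = 1e-9)
})

test_that("smoothing windows never leak across chromosomes", {
  scan <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 50),
    pos = rep(seq(1e4, 5e6, length.out = 50), 2),
    ed = c(rep(1, 50), rep(0, 50)),
    delta_snp_index = c(rep(0.9, 50), rep(0, 50)))
  fit <- fit_scan(scan, half_width_bp = 2e6, min_window_snps = 1)
  expect_true(all(fit$fitted_ed[fit$chrom == "chr2"] == 0))
  expect_true(all(fit$fitted_delta[fit$chrom == "chr2"] == 0))
  expect_true(all(fit$fitted_ed[fit$chrom == "chr1"] == 1))
})

test_that("fitted values match a brute-force kernel recomputation", {
  set.seed(19)
  n <- 800
  pos <- sort(sample(1:3e7, n))
  scan <- tibble::tibble(chrom = "chr1", pos = pos,
                         ed = runif(n, 0, 1.2), delta_snp_index = runif(n, -1, 1))
  fit <- suppressMessages(fit_scan(scan, half_width_bp = 8e5, ed_power = 4,
                                   min_window_snps = 3))
  expect_equal(fit$fitted_ed, oracle_tricube(pos, scan$ed^4, 8e5, 3),
               tolerance = 1e-9)
  expect_equal(fit$fitted_delta,
               oracle_tricube(pos, scan$delta_snp_index, 8e5, 3),
               tolerance = 1e-9)
})

test_that("underfilled windows yield NA fitted values", {
  scan <- tibble::tibble(chrom = "chr1", pos = c(1e4, 2e4, 2e7),
                         ed = c(1, 1, 1), delta_snp_index = 0)
  expect_message(fit <- fit_scan(scan, half_width_bp = 1e5, min_window_snps = 2),
                 "undefined")
  expect_true(is.na(fit$fitted_ed[3]))   # isolated SNP
  expect_false(anyNA(fit$fitted_ed[1:2]))
})
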