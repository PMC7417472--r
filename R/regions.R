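#' Construct a genomic-region table
#'
#' Regions are 1-based inclusive intervals tagged with the method that
#' produced them; `size_mb` is `(end - start) / 1e6` rounded to 2 decimals,
#' matching how QTL-seq region tables report physical size.
#'
#' @param chrom,start_bp,end_bp Vectors of equal length (1-based inclusive).
#' @param method Method label(s): `"delta_snp_index"`, `"ed"` or `"common"`.
#' @return Tibble `chrom`, `start_bp`, `end_bp`, `method`, `size_mb`.
#' @export
#' @examples
#' region_table("chr7", 20160000, 24330000, "common")$size_mb  # 4.17
region_table <- function(chrom, start_bp, end_bp, method) {
  if (any(start_bp > end_bp)) abort("region start_bp must be <= end_bp")
  if (any(start_bp < 1)) abort("region coordinates are 1-based: start_bp >= 1")
  tibble(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
         method = method, size_mb = round((end_bp - start_bp) / 1e6, 2))
}

#' Call candidate regions from a fitted genome scan
#'
#' Identifies maximal runs of consecutive SNPs whose fitted statistic passes
#' the significance rule, merges runs separated by at most `merge_gap_bp`,
#' and reports the outermost passing SNP positions as region bounds.
#'
#' Rules: for `method = "delta"` a SNP passes when
#' `|fitted_delta| > ci` at the chosen confidence level (the per-marker
#' simulated null bound, see [delta_null_bounds()]); for `method = "ed"`
#' when `fitted_ed > threshold` (see [ed_threshold()]). Delta-method region
#' bounds are rounded outward to a 10-kb grid — the convention of
#' window-based delta SNP-index reporting — while ED regions keep raw SNP
#' positions.
#'
#' @param scan Fitted scan tibble; for `"delta"` it must carry a `ci95` (and
#'   for `ci_level = "ci99"` a `ci99`) column, e.g. merged in from
#'   [delta_null_bounds()].
#' @param method `"delta"` or `"ed"`.
#' @param threshold Scalar ED threshold (required for `"ed"`).
#' @param ci_level `"ci95"` (default) or `"ci99"` for the delta rule.
#' @param merge_gap_bp Merge passing runs separated by at most this many bp
#'   (default 500 kb).
#' @param round_to_bp Grid for outward rounding of delta-method bounds
#'   (default 10 kb; ignored for ED).
#' @return A region tibble as from [region_table()]; empty (0 rows) when no
#'   SNP passes.
#' @export
call_regions <- function(scan, method = c("delta", "ed"), threshold = NULL,
                         ci_level = c("ci95", "ci99"),
                         merge_gap_bp = 5e5, round_to_bp = 1e4) {
  method <- match.arg(method)
  ci_level <- match.arg(ci_level)
  scan <- arrange(as_tibble(scan), .data$chrom, .data$pos)

  if (method == "delta") {
    stopifnot("fitted_delta" %in% names(scan), ci_level %in% names(scan))
    pass <- !is.na(scan$fitted_delta) &
      abs(scan$fitted_delta) > scan[[ci_level]]
    label <- "delta_snp_index"
  } else {
    stopifnot("fitted_ed" %in% names(scan))
    if (is.null(threshold)) abort("ED region calling requires `threshold`")
    pass <- !is.na(scan$fitted_ed) & scan$fitted_ed > threshold
    label <- "ed"
  }

  empty <- region_table(character(), numeric(), numeric(), character())
  if (!any(pass)) return(empty)

  runs <- scan[pass, c("chrom", "pos"), drop = FALSE]
  idx <- which(pass)
  # maximal runs of consecutive passing SNPs within a chromosome
  new_run <- c(TRUE, diff(idx) != 1L | runs$chrom[-1] != runs$chrom[-nrow(runs)])
  runs$run <- cumsum(new_run)
  spans <- runs |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1], start_bp = min(.data$pos),
              end_bp = max(.data$pos), .groups = "drop")

  # merge runs on the same chromosome separated by <= merge_gap_bp
  spans <- arrange(spans, .data$chrom, .data$start_bp)
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(spans))) {
    row <- spans[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom &&
        row$start_bp - cur$end_bp <= merge_gap_bp) {
      cur$end_bp <- max(cur$end_bp, row$end_bp)
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- row[, c("chrom", "start_bp", "end_bp")]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- dplyr::bind_rows(merged)

  if (method == "delta" && !is.null(round_to_bp) && round_to_bp > 1) {
    out$start_bp <- pmax(1, floor(out$start_bp / round_to_bp) * round_to_bp)
    out$end_bp <- ceiling(out$end_bp / round_to_bp) * round_to_bp
  }
  region_table(out$chrom, out$start_bp, out$end_bp, label)
}

#' Intersect two region sets: the common candidate region
#'
#' The candidate region of a two-method scan is the overlap of the regions
#' called by the delta SNP-index and ED methods. Every same-chromosome pair
#' with a positive-length overlap contributes `[max(starts), min(ends)]`,
#' labelled `"common"`; results are de-duplicated and sorted by
#' `(chrom, start_bp)`.
#'
#' @param a,b Region tibbles (see [region_table()]).
#' @return A region tibble of the pairwise overlaps (possibly empty).
#' @export
#' @examples
#' d <- region_table("chr7", 20160000, 24330000, "delta_snp_index")
#' e <- region_table("chr7", 12547138, 26674659, "ed")
#' intersect_region_sets(d, e)
intersect_region_sets <- function(a, b) {
  need <- c("chrom", "start_bp", "end_bp")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  empty <- region_table(character(), numeric(), numeric(), character())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)

  pairs <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  ov <- tibble(
    chrom = a$chrom[pairs$i],
    start_bp = pmax(a$start_bp[pairs$i], b$start_bp[pairs$j]),
    end_bp = pmin(a$end_bp[pairs$i], b$end_bp[pairs$j]),
    same = a$chrom[pairs$i] == b$chrom[pairs$j]
  ) |>
    filter(.data$same, .data$end_bp > .data$start_bp) |>
    distinct(.data$chrom, .data$start_bp, .data$end_bp) |>
    arrange(.data$chrom, .data$start_bp)
  if (nrow(ov) == 0) return(empty)
  region_table(ov$chrom, ov$start_bp, ov$end_bp, "common")
}

#' Convert region coordinates between dialects
#'
#' Internally regions are 1-based inclusive; BED is 0-based half-open.
#' Round-tripping is the identity and interval length is preserved
#' (`bed_end - bed_start == end_bp - start_bp + 1`).
#'
#' @param regions A region tibble.
#' @param to `"bed_0based_halfopen"` or `"internal_1based_inclusive"`.
#' @return The tibble with `start_bp`/`end_bp` re-expressed in the target
#'   dialect and a `coord_dialect` attribute recording it.
#' @export
#' @examples
#' r <- region_table("chr7", 20160000, 24330000, "common")
#' convert_coordinates(r, "bed_0based_halfopen")
convert_coordinates <- function(regions,
                                to = c("bed_0based_halfopen",
                                       "internal_1based_inclusive")) {
  to <- match.arg(to)
  from <- attr(regions, "coord_dialect") %||% "internal_1based_inclusive"
  out <- as_tibble(regions)
  if (from != to) {
    if (to == "bed_0based_halfopen") {
      out$start_bp <- out$start_bp - 1
    } else {
      out$start_bp <- out$start_bp + 1
    }
  }
  attr(out, "coord_dialect") <- to
  out
}
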