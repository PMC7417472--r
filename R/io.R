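# Format readers and writers. VCF parsing goes through vcfR, GFF3 through
# ape::read.gff; the TSV dialects are documented in the README.

#' Read per-SNP allele depths from VCF or TSV
#'
#' Reads biallelic SNP records with per-pool allele depths and applies the
#' standard BSA quality filters: per-pool minimum total depth, a per-pool
#' maximum-depth percentile cap (repeat-region guard), and — when parent
#' samples are present — the requirement that the two parents be homozygous
#' for different alleles (the informative-marker condition). Filter counts
#' are reported and attached as the `filter_counts` attribute.
#'
#' Accepted inputs:
#' * VCF with an `AD` FORMAT field (`ref,alt` counts) and samples named
#'   `T_POOL` and `S_POOL` (optionally `P_TOL`, `P_SENS` parents, or pass
#'   `parent_samples`).
#' * TSV with header `chrom pos ref alt t_ref t_alt s_ref s_alt`
#'   (optionally `p1_ref p1_alt p2_ref p2_alt` for the tolerant/sensitive
#'   parents); `#` lines are comments.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param min_depth Minimum total depth per pool (default 7).
#' @param max_depth_quantile Per-pool depth percentile cap (default 0.99;
#'   `NULL` disables).
#' @param pool_samples,parent_samples VCF sample names for the T/S pools and
#'   (optionally) the tolerant/sensitive parents.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `t_ref`, `t_alt`, `s_ref`,
#'   `s_alt` of records passing all filters, with a `filter_counts`
#'   attribute.
#' @export
read_allele_depths <- function(path, format = c("auto", "vcf", "tsv"),
                               min_depth = 7, max_depth_quantile = 0.99,
                               pool_samples = c("T_POOL", "S_POOL"),
                               parent_samples = c("P_TOL", "P_SENS")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  raw <- if (format == "vcf") {
    .read_depths_vcf(path, pool_samples, parent_samples)
  } else {
    .read_depths_tsv(path)
  }

  counts <- c(read = nrow(raw), malformed = attr(raw, "n_malformed") %||% 0L,
              multiallelic = attr(raw, "n_multiallelic") %||% 0L)

  has_parents <- all(c("p1_ref", "p1_alt", "p2_ref", "p2_alt") %in% names(raw))
  t_depth <- raw$t_ref + raw$t_alt
  s_depth <- raw$s_ref + raw$s_alt

  keep <- t_depth >= min_depth & s_depth >= min_depth
  counts["low_depth"] <- sum(!keep)
  if (!is.null(max_depth_quantile)) {
    cap_t <- quantile(t_depth, max_depth_quantile, names = FALSE)
    cap_s <- quantile(s_depth, max_depth_quantile, names = FALSE)
    over <- t_depth > cap_t | s_depth > cap_s
    counts["high_depth"] <- sum(over & keep)
    keep <- keep & !over
  } else counts["high_depth"] <- 0L

  if (has_parents) {
    # informative marker: parents homozygous for different alleles
    p1 <- raw$p1_alt / pmax(raw$p1_ref + raw$p1_alt, 1)
    p2 <- raw$p2_alt / pmax(raw$p2_ref + raw$p2_alt, 1)
    hom1 <- p1 <= 0.1 | p1 >= 0.9
    hom2 <- p2 <= 0.1 | p2 >= 0.9
    informative <- hom1 & hom2 & (abs(p1 - p2) >= 0.8)
    counts["parent_uninformative"] <- sum(!informative & keep)
    keep <- keep & informative
  } else {
    inform("no parent columns: SNP orientation falls back to reference/alternate alleles")
  }

  out <- as_tibble(raw)[keep, c("chrom", "pos", "ref", "alt",
                                "t_ref", "t_alt", "s_ref", "s_alt")]
  counts["kept"] <- nrow(out)
  inform(paste0("allele depths: ", paste(names(counts), counts,
                                         sep = "=", collapse = ", ")))
  if (nrow(out) == 0) abort("no allele-depth records passed the filters")
  attr(out, "filter_counts") <- counts
  out
}

.read_depths_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "s_ref", "s_alt")
  if (!all(need %in% names(df)))
    abort(paste0("allele-depth TSV must have columns: ",
                 paste(need, collapse = ", ")))
  num <- intersect(c(need[-(1:4)], "p1_ref", "p1_alt", "p2_ref", "p2_alt"),
                   names(df))
  bad <- !complete.cases(df[, c("chrom", "pos", num)]) |
    rowSums(as.matrix(df[, num]) < 0, na.rm = TRUE) > 0
  if (any(bad)) warn(sprintf("%d malformed TSV record(s) skipped", sum(bad)))
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_malformed") <- sum(bad)
  out
}

.read_depths_vcf <- function(path, pool_samples, parent_samples) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (!all(pool_samples %in% colnames(ad)))
    abort(paste0("VCF must contain pool samples ",
                 paste(pool_samples, collapse = " and ")))

  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    warn(sprintf("%d non-biallelic-SNP record(s) skipped", n_multi))

  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "NA,NA", x), ",", fixed = TRUE)
    ref <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
    list(ref = ref, alt = alt)
  }
  t_ad <- split_ad(ad[, pool_samples[1]])
  s_ad <- split_ad(ad[, pool_samples[2]])

  out <- tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    t_ref = t_ad$ref, t_alt = t_ad$alt,
    s_ref = s_ad$ref, s_alt = s_ad$alt
  )
  if (all(parent_samples %in% colnames(ad))) {
    p1 <- split_ad(ad[, parent_samples[1]])
    p2 <- split_ad(ad[, parent_samples[2]])
    out$p1_ref <- p1$ref; out$p1_alt <- p1$alt
    out$p2_ref <- p2$ref; out$p2_alt <- p2$alt
  }
  malformed <- !complete.cases(out[, c("t_ref", "t_alt", "s_ref", "s_alt")])
  if (any(malformed & biallelic))
    warn(sprintf("%d record(s) with unparseable AD skipped",
                 sum(malformed & biallelic)))
  res <- out[biallelic & !malformed, , drop = FALSE]
  attr(res, "n_malformed") <- sum(malformed & biallelic)
  attr(res, "n_multiallelic") <- n_multi
  res
}

#' Write allele depths as TSV
#'
#' @param depths Allele-depth tibble (truth columns, if present, dropped).
#' @param path Output file.
#' @param seed,config_hash Provenance recorded in the `#` header line.
#' @return `path`, invisibly.
#' @export
write_allele_depths_tsv <- function(depths, path, seed = NA, config_hash = "") {
  cols <- intersect(c("chrom", "pos", "ref", "alt",
                      "t_ref", "t_alt", "s_ref", "s_alt"), names(depths))
  readr::write_lines(output_header(seed, config_hash), path)
  readr::write_tsv(depths[, cols], path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write allele depths as a minimal VCF
#'
#' Emits biallelic SNP records with a per-sample `AD` (`ref,alt`) FORMAT
#' field for samples `T_POOL` and `S_POOL`, 1-based positions.
#'
#' @inheritParams write_allele_depths_tsv
#' @return `path`, invisibly.
#' @export
write_allele_depths_vcf <- function(depths, path, seed = NA, config_hash = "") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=bsaqtl_%s", utils::packageVersion("bsaqtl")),
    sprintf("##bsaqtl_seed=%s", format(seed)),
    sprintf("##bsaqtl_config_hash=%s", config_hash),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "T_POOL", "S_POOL"), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  depths$chrom, as.integer(depths$pos), depths$ref, depths$alt,
                  as.integer(depths$t_ref), as.integer(depths$t_alt),
                  as.integer(depths$s_ref), as.integer(depths$s_alt))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 files are parsed with `ape::read.gff` and restricted to rows of type
#' `gene`, with the gene id taken from the `ID=` attribute. BED input (BED6
#' or more) is converted from 0-based half-open to 1-based inclusive
#' coordinates.
#'
#' @param path Input file (`.gff`/`.gff3` or `.bed`).
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "gff3") {
    gff <- ape::read.gff(path)
    genes <- gff[gff$type == "gene", , drop = FALSE]
    id <- sub("^.*ID=([^;]+).*$", "\\1", genes$attributes)
    tibble(gene_id = id, chrom = as.character(genes$seqid),
           start = as.numeric(genes$start), end = as.numeric(genes$end),
           strand = as.character(genes$strand))
  } else {
    bed <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
    if (ncol(bed) < 4) abort("BED gene models need at least 4 columns")
    tibble(gene_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
           start = as.numeric(bed[[2]]) + 1, end = as.numeric(bed[[3]]),
           strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else ".")
  }
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output file.
#' @param seed,config_hash Provenance recorded in a comment line.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path, seed = NA, config_hash = "") {
  lines <- c("##gff-version 3",
             output_header(seed, config_hash),
             sprintf("%s\tbsaqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start),
                     as.integer(genes$end),
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene_id))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a DEG table
#'
#' TSV with header `gene_id contrast log2_ratio fdr`; significance and
#' direction are (re)derived with [classify_deg()].
#'
#' @param path Input TSV.
#' @return Tibble `gene_id`, `contrast`, `log2_ratio`, `fdr`, `significant`,
#'   `direction`.
#' @export
read_deg_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("gene_id", "contrast", "log2_ratio", "fdr")
  if (!all(need %in% names(df)))
    abort(paste0("DEG table must have columns: ", paste(need, collapse = ", ")))
  dplyr::bind_cols(as_tibble(df)[need], classify_deg(df$log2_ratio, df$fdr))
}

#' Read a phenotype table
#'
#' TSV with header `line_id trait control_value treatment_value`.
#'
#' @param path Input TSV.
#' @return Tibble of the four columns.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("line_id", "trait", "control_value", "treatment_value")
  if (!all(need %in% names(df)))
    abort(paste0("phenotype table must have columns: ",
                 paste(need, collapse = ", ")))
  as_tibble(df)[need]
}

#' Write called regions as BED and as a readable region table
#'
#' The BED file uses 0-based half-open coordinates (via
#' [convert_coordinates()]); the companion table mirrors the conventional
#' QTL-seq report (Method, Chromosome, Start, End, Size in Mb) in 1-based
#' inclusive coordinates.
#'
#' @param regions Region tibble.
#' @param bed_path,table_path Output files (either may be `NULL` to skip).
#' @param seed,config_hash Provenance for the header line.
#' @return Invisibly, a list of the written paths.
#' @export
write_regions <- function(regions, bed_path = NULL, table_path = NULL,
                          seed = NA, config_hash = "") {
  if (!is.null(bed_path)) {
    bed <- convert_coordinates(regions, "bed_0based_halfopen")
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.", bed$chrom,
                     as.integer(bed$start_bp), as.integer(bed$end_bp),
                     bed$method)
    readr::write_lines(c(output_header(seed, config_hash), lines), bed_path)
  }
  if (!is.null(table_path)) {
    tab <- tibble(Method = regions$method, Chromosome = regions$chrom,
                  Start = regions$start_bp, End = regions$end_bp,
                  Size_Mb = regions$size_mb)
    readr::write_lines(output_header(seed, config_hash), table_path)
    readr::write_tsv(tab, table_path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(list(bed = bed_path, table = table_path))
}

#' Write the per-SNP scan table as TSV
#'
#' @param scan Scan tibble (any stage: raw, fitted, with null bounds).
#' @param path Output file.
#' @param seed,config_hash Provenance for the header line.
#' @param delta_convention Sign convention recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path, seed = NA, config_hash = "",
                           delta_convention = attr(scan, "delta_convention")) {
  hdr <- c(output_header(seed, config_hash),
           sprintf("# delta_snp_index convention: %s",
                   delta_convention %||% "s_minus_t"))
  readr::write_lines(hdr, path)
  readr::write_tsv(as_tibble(scan), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read and write flat key-value configuration files
#'
#' The pipeline configuration is a flat `key = value` text file with
#' stage-prefixed keys (e.g. `sim.n_lines = 983`); `#` starts a comment.
#' Values are coerced to numeric where possible, `TRUE`/`FALSE` to logical.
#'
#' @param path File to read or write.
#' @return `read_flat_config()`: a named list; `write_flat_config()`:
#'   `path`, invisibly.
#' @export
read_flat_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) abort(sprintf("malformed config line(s): %s",
                              paste(lines[bad], collapse = "; ")))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  coerce <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  setNames(lapply(vals, coerce), keys)
}

#' @rdname read_flat_config
#' @param config Named list (scalars) to serialize.
#' @export
write_flat_config <- function(config, path) {
  flat <- unlist(config)
  readr::write_lines(sprintf("%s = %s", names(flat), as.character(flat)), path)
  invisible(path)
}
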