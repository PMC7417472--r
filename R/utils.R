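# Internal helpers: seeded stage streams, config hashing, output headers.

# Named per-stage seed streams derived from one user seed, so stages can be
# re-run independently yet reproducibly. Offsets are fixed per stage name.
.stage_offsets <- c(
  cross = 11L, bulks = 23L, depths = 37L, genes = 53L, deg = 71L,
  null = 97L, scan = 113L, pipeline = 131L
)

stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  off <- .stage_offsets[[stage]]
  if (is.null(off)) abort(paste0("unknown seed stream: ", stage))
  # keep the derived seed well inside 32-bit integer range
  as.integer((abs(seed) + off * 1000003) %% 2147483587)
}

config_hash <- function(config) {
  rlang::hash(config)
}

# "# bsaqtl <version>; seed=...; config_hash=..." header written atop every
# output file so any table can be traced back to its run.
output_header <- function(seed, hash) {
  sprintf("# bsaqtl %s; seed=%s; config_hash=%s",
          as.character(utils::packageVersion("bsaqtl")), format(seed), hash)
}

abort_config <- function(field, why) {
  abort(sprintf("invalid configuration: `%s` %s", field, why),
        class = "bsaqtl_config_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
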