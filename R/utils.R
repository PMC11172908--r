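#' @keywords internal
"_PACKAGE"

#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats coef cor lm median pf quantile rnbinom rpois runif rnorm plogis sd setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (values here are nonnegative copy numbers).
round_half_up <- function(x) floor(x + 0.5)

# Window identifier in 1-based inclusive locus notation, e.g. "3:7638801-7679600".
region_id <- function(chrom, start0, end0) {
  sprintf("%s:%d-%d", chrom, as.integer(start0) + 1L, as.integer(end0))
}

# Parse "chrom:start-end" (1-based inclusive) back to 0-based half-open coords.
parse_region_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed region id: ", id[bad][1])
  data.frame(
    chrom = vapply(m, `[`, character(1), 2L),
    start = vapply(m, function(x) as.numeric(x[3]), numeric(1)) - 1,
    end   = vapply(m, function(x) as.numeric(x[4]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Exact 32-bit FNV-1a hash of a character scalar. Used for manifest parameter
# hashes and per-stage seed derivation; no cryptographic intent. The multiply
# is split into 16-bit halves so every intermediate stays exactly
# representable in a double.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    top <- h %/% 2147483648
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b)) + top * 2147483648
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  h
}

# Derive a child seed (< 2^31) from a base seed and a stage label, so stages
# are reproducible when rerun standalone.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + fnv1a(label)) %% 2147483647)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
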