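#' Tile a genome into fixed-width windows with a smooth GC profile
#'
#' Builds the coordinate backbone used by every downstream stage: each
#' chromosome is tiled left to right with non-overlapping windows of
#' `window_size` bp (the last window of a chromosome may be shorter). Each
#' window carries a GC fraction drawn from a smooth spatial process bounded
#' in (0.2, 0.8), and a mask flag marking low-complexity-like windows that
#' are simulated with erratic depth and excluded from all statistics.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   every length must be at least `window_size`.
#' @param window_size window width in bp (default 800).
#' @param gc_profile_seed integer seed for the GC process and mask placement.
#' @param mask_fraction fraction of windows flagged as masked (default 0.02).
#' @return An object of class `windowed_genome`: a list with `windows`
#'   (data.frame `chrom`, `start`, `end` in 0-based half-open bp, `gc`,
#'   `masked`), `window_size` and `chrom_lengths`.
#' @examples
#' g <- make_windowed_genome(c(chr1 = 8000), window_size = 800)
#' nrow(g$windows)  # 10
#' @export
make_windowed_genome <- function(chrom_lengths, window_size = 800,
                                 gc_profile_seed = 1L, mask_fraction = 0.02) {
  if (length(chrom_lengths) == 0)
    stop("configuration error: chrom_lengths is empty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("configuration error: chrom_lengths must be named")
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0)
    stop("configuration error: window_size must be a positive number")
  if (any(chrom_lengths < window_size))
    stop("configuration error: every chromosome must be at least one window long")

  set.seed(gc_profile_seed)
  pieces <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    n <- length(starts)
    # AR(1) latent process squashed into (0.2, 0.8): smooth along the
    # chromosome, bounded, seeded.
    z <- numeric(n)
    z[1] <- rnorm(1)
    if (n > 1) {
      eps <- rnorm(n - 1, sd = 0.25)
      for (i in 2:n) z[i] <- 0.97 * z[i - 1] + eps[i - 1]
    }
    gc <- 0.2 + 0.6 * plogis(z)
    data.frame(chrom = chrom, start = starts, end = ends, gc = gc,
               masked = FALSE, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, pieces)
  n_mask <- round(mask_fraction * nrow(windows))
  if (n_mask > 0)
    windows$masked[sample(nrow(windows), n_mask)] <- TRUE
  rownames(windows) <- NULL

  structure(
    list(windows = windows, window_size = window_size,
         chrom_lengths = chrom_lengths),
    class = "windowed_genome"
  )
}

#' @export
print.windowed_genome <- function(x, ...) {
  cat(sprintf(
    "windowed_genome: %d chromosome(s), %d windows of %d bp (%d masked)\n",
    length(x$chrom_lengths), nrow(x$windows), as.integer(x$window_size),
    sum(x$windows$masked)))
  invisible(x)
}

# Canonical column ids ("chrom:start-end", 1-based inclusive) for a genome's
# windows; used as matrix colnames throughout.
window_ids <- function(genome) {
  with(genome$windows, region_id(chrom, start, end))
}

# Map a 0-based half-open interval to the window index range it spans.
# Errors when boundaries do not coincide with window boundaries and
# `exact = TRUE`.
interval_to_window_range <- function(genome, chrom, start, end, exact = TRUE) {
  w <- genome$windows
  idx <- which(w$chrom == chrom & w$end > start & w$start < end)
  if (length(idx) == 0)
    stop("specification error: interval ", chrom, ":", start, "-", end,
         " is off the genome")
  if (exact &&
      (w$start[idx[1]] != start || w$end[idx[length(idx)]] != end))
    stop("specification error: interval ", chrom, ":", start, "-", end,
         " is not aligned to window boundaries")
  idx
}

#' Write and read the window table as BED-like TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `gc`, `masked`.
#'
#' @param genome a `windowed_genome`.
#' @param path output file.
#' @return `write_windows` returns `path` invisibly; `read_windows` returns
#'   a `windowed_genome` (window size inferred from the modal window width).
#' @export
write_windows <- function(genome, path) {
  write_tsv(genome$windows, path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  w <- read_tsv(path)
  w$masked <- as.logical(w$masked)
  widths <- w$end - w$start
  window_size <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
  lens <- tapply(w$end, w$chrom, max)
  chrom_lengths <- as.numeric(lens)
  names(chrom_lengths) <- names(lens)
  structure(
    list(windows = w, window_size = window_size, chrom_lengths = chrom_lengths),
    class = "windowed_genome"
  )
}
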