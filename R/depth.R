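#' GC-bias correction of a read-depth matrix
#'
#' Median-ratio correction within GC bins: for each sample, unmasked windows
#' are grouped into `n_bins` equal-width GC bins (computed once over the
#' observed GC range); values in a bin are scaled by
#' `global median / bin median`. Bins whose median is zero are left
#' unchanged and reported in the `"zero_bins"` attribute. Masked windows are
#' carried through untouched.
#'
#' @param depth samples x windows numeric matrix (see [simulate_depth()]).
#' @param genome the `windowed_genome` the matrix columns follow.
#' @param n_bins number of GC bins (default 20).
#' @return corrected matrix, same shape and dimnames as `depth`.
#' @export
gc_correct <- function(depth, genome, n_bins = 20) {
  if (!is.matrix(depth) || nrow(depth) == 0 || ncol(depth) == 0)
    stop("input error: depth matrix is empty")
  stopifnot(ncol(depth) == nrow(genome$windows))
  unmasked <- !genome$windows$masked
  gc <- genome$windows$gc
  rng <- range(gc[unmasked])
  if (diff(rng) == 0) {
    bin <- rep(1L, length(gc))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }

  corrected <- depth
  zero_bins <- integer(0)
  for (s in seq_len(nrow(depth))) {
    x <- depth[s, ]
    gmed <- median(x[unmasked])
    for (b in unique(bin[unmasked])) {
      sel <- unmasked & bin == b
      bmed <- median(x[sel])
      if (bmed == 0) {
        zero_bins <- union(zero_bins, b)
        next
      }
      corrected[s, sel] <- x[sel] * (gmed / bmed)
    }
  }
  attr(corrected, "zero_bins") <- sort(zero_bins)
  corrected
}

#' Convert corrected depth to absolute copy number
#'
#' Rescales each sample so its median over unmasked windows equals the
#' diploid state: `cn[s, w] = 2 * depth[s, w] / median_w(depth[s, .])`.
#' Masked windows become `NA` (the sentinel excluded from all statistics).
#'
#' @param corrected samples x windows depth matrix (after [gc_correct()]).
#' @param genome the matching `windowed_genome`.
#' @return samples x windows absolute copy number matrix.
#' @export
normalize_copy_number <- function(corrected, genome) {
  stopifnot(is.matrix(corrected), ncol(corrected) == nrow(genome$windows))
  unmasked <- !genome$windows$masked
  meds <- apply(corrected[, unmasked, drop = FALSE], 1, median)
  if (any(meds <= 0)) {
    bad <- rownames(corrected)[which(meds <= 0)[1]]
    stop("input error: sample '", bad, "' has non-positive median depth")
  }
  cn <- 2 * corrected / meds
  cn[, !unmasked] <- NA_real_
  cn
}

# Bridge same-kind seed runs separated by <= max_gap neutral positions and
# return a data.frame of runs (first/last seed index within `idx` ordering).
merge_seed_runs <- function(seed_pos, max_gap) {
  if (length(seed_pos) == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  breaks <- which(diff(seed_pos) > max_gap + 1)
  from <- seed_pos[c(1, breaks + 1)]
  to <- seed_pos[c(breaks, length(seed_pos))]
  data.frame(from = from, to = to)
}

#' Call per-sample CNV segments from a copy number matrix
#'
#' Windows with `cn <= loss_max` (resp. `>= gain_min`) seed loss (gain)
#' segments; same-kind seeds separated by at most `max_gap_windows` neutral
#' or masked windows are merged into one segment; segments spanning fewer
#' than `min_windows` windows are dropped. Segments never cross chromosome
#' boundaries, never overlap within a sample, and are sorted.
#'
#' @param cn samples x windows copy number matrix (masked windows `NA`).
#' @param genome the matching `windowed_genome`.
#' @param loss_max,gain_min seed thresholds, must satisfy
#'   `loss_max < 2 < gain_min` (defaults 1.5 and 2.5, the midpoints between
#'   integer copy states).
#' @param min_windows minimum segment span in windows (default 2).
#' @param max_gap_windows neutral windows bridged inside a segment
#'   (default 1).
#' @return data.frame `sample`, `chrom`, `start`, `end` (0-based half-open),
#'   `kind`, `mean_cn` (mean over unmasked spanned windows), `n_windows`.
#' @export
call_sample_cnvs <- function(cn, genome, loss_max = 1.5, gain_min = 2.5,
                             min_windows = 2, max_gap_windows = 1) {
  if (!(loss_max < 2 && gain_min > 2))
    stop("configuration error: need loss_max < 2 < gain_min")
  w <- genome$windows
  chrom_idx <- split(seq_len(nrow(w)), w$chrom)
  samples <- rownames(cn)
  out <- list()
  for (s in seq_len(nrow(cn))) {
    row <- cn[s, ]
    for (idx in chrom_idx) {
      x <- row[idx]
      state <- ifelse(is.na(x), "neutral",
                      ifelse(x <= loss_max, "loss",
                             ifelse(x >= gain_min, "gain", "neutral")))
      for (kind in c("loss", "gain")) {
        # positions of this kind, but runs must not bridge across an
        # opposite-kind seed: split at opposite seeds first
        opp <- if (kind == "loss") "gain" else "loss"
        pos <- which(state == kind)
        if (length(pos) == 0) next
        opp_pos <- which(state == opp)
        seg_id <- findInterval(pos, opp_pos)  # runs between opposite seeds
        for (g in split(pos, seg_id)) {
          runs <- merge_seed_runs(g, max_gap_windows)
          for (r in seq_len(nrow(runs))) {
            span <- runs$from[r]:runs$to[r]
            if (length(span) < min_windows) next
            gidx <- idx[span]
            vals <- row[gidx]
            out[[length(out) + 1]] <- data.frame(
              sample = samples[s], chrom = w$chrom[gidx[1]],
              start = w$start[gidx[1]], end = w$end[gidx[length(gidx)]],
              kind = kind, mean_cn = mean(vals, na.rm = TRUE),
              n_windows = length(span), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      kind = character(0), mean_cn = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$sample, calls$chrom, calls$start), ]
  rownames(calls) <- NULL
  calls
}

#' Write / read per-sample CNV calls as BED5+ TSV
#'
#' Columns: chrom, start, end, sample, kind, mean_cn, n_windows.
#' @param calls data.frame from [call_sample_cnvs()].
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  write_tsv(calls[, c("chrom", "start", "end", "sample", "kind",
                      "mean_cn", "n_windows")], path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_tsv(path)
  df[, c("sample", "chrom", "start", "end", "kind", "mean_cn", "n_windows")]
}

#' Write / read a samples x windows matrix as TSV
#'
#' First column `sample`, one column per window keyed "chrom:start-end".
#' @param m numeric matrix with sample rownames and window-id colnames.
#' @param path file path.
#' @export
write_depth_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}
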