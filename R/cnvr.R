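#' Configuration for CNVR construction
#'
#' @param min_variant_freq fraction of samples that must deviate from the
#'   diploid state in a window for it to be a CNVR candidate (strictly
#'   exceeded; default 0.05).
#' @param corr_min minimum Pearson correlation of per-sample mean copy
#'   number between neighboring intervals for them to merge (default 0.5).
#' @param max_gap_windows unflagged windows bridged inside a candidate run
#'   (default 1).
#' @param merge_dist_windows maximum separation, in windows, at which two
#'   intervals are considered neighbors for correlation merging (default 3).
#' @param min_call_windows minimum span (in windows) a per-sample call must
#'   have to count as population evidence in [candidate_windows()]
#'   (default 3): two-window calls arise by chance dozens of times per
#'   sample at realistic coverage and would otherwise flood the population
#'   frequency threshold.
#' @return list of class `merge_config`.
#' @export
merge_config <- function(min_variant_freq = 0.05, corr_min = 0.5,
                         max_gap_windows = 1, merge_dist_windows = 3,
                         min_call_windows = 3) {
  if (!(min_variant_freq > 0 && min_variant_freq < 1))
    stop("configuration error: min_variant_freq must be in (0, 1)")
  if (corr_min < -1 || corr_min > 1)
    stop("configuration error: corr_min must be in [-1, 1]")
  structure(list(min_variant_freq = min_variant_freq, corr_min = corr_min,
                 max_gap_windows = max_gap_windows,
                 merge_dist_windows = merge_dist_windows,
                 min_call_windows = min_call_windows),
            class = "merge_config")
}

#' Flag windows with population-level copy number variation
#'
#' A window is flagged when the fraction of samples deviating from the
#' diploid state (`|cn - 2| >= 0.5`) strictly exceeds `min_variant_freq`.
#' When per-sample CNV `calls` are supplied, a sample only counts as
#' deviating in a window if the window also lies inside one of that
#' sample's calls spanning at least `cfg$min_call_windows` windows: the
#' run-length requirement is what makes a small population frequency
#' threshold usable on noisy per-window copy numbers. Masked windows are
#' never flagged.
#'
#' @param cn samples x windows copy number matrix.
#' @param genome the matching `windowed_genome`.
#' @param cfg a [merge_config()].
#' @param calls optional data.frame from [call_sample_cnvs()].
#' @return logical vector, one flag per window.
#' @export
candidate_windows <- function(cn, genome, cfg = merge_config(), calls = NULL) {
  dev <- !is.na(cn) & abs(cn - 2) >= 0.5
  if (!is.null(calls)) {
    calls <- calls[calls$n_windows >= cfg$min_call_windows, , drop = FALSE]
  }
  if (!is.null(calls) && nrow(calls) > 0) {
    incall <- matrix(FALSE, nrow = nrow(cn), ncol = ncol(cn),
                     dimnames = dimnames(cn))
    w <- genome$windows
    sidx <- match(calls$sample, rownames(cn))
    for (i in seq_len(nrow(calls))) {
      widx <- which(w$chrom == calls$chrom[i] &
                    w$start >= calls$start[i] & w$end <= calls$end[i])
      incall[sidx[i], widx] <- TRUE
    }
    dev <- dev & incall
  } else if (!is.null(calls)) {
    dev[] <- FALSE
  }
  support <- colSums(dev)
  support[genome$windows$masked] <- 0L
  flags <- support / nrow(cn) > cfg$min_variant_freq
  attr(flags, "support") <- support
  flags
}

#' Merge flagged windows into raw CNVR intervals
#'
#' Maximal runs of flagged windows (with up to `max_gap_windows` unflagged
#' windows bridged) become intervals; neighboring intervals on the same
#' chromosome separated by at most `merge_dist_windows` windows are merged
#' when the Pearson correlation of their per-sample mean copy number
#' vectors is at least `corr_min`. When the flags carry the per-window
#' deviating-sample counts (the `"support"` attribute set by
#' [candidate_windows()]), interval boundaries are refined: terminal
#' windows supported by fewer than half the interval's median support are
#' trimmed, so a handful of samples whose calls bleed one or two windows
#' past a variant's true edge cannot stretch the population boundary.
#'
#' @inheritParams candidate_windows
#' @param flags logical per-window flags from [candidate_windows()].
#' @return data.frame `chrom`, `start`, `end`, `first_window`, `last_window`
#'   (window indices), sorted and non-overlapping.
#' @export
merge_to_cnvrs <- function(flags, cn, genome, cfg = merge_config()) {
  support <- attr(flags, "support")
  stopifnot(length(flags) == ncol(cn))
  w <- genome$windows
  out <- list()
  for (chrom in unique(w$chrom)) {
    idx <- which(w$chrom == chrom)
    pos <- which(flags[idx])
    runs <- merge_seed_runs(pos, cfg$max_gap_windows)
    if (nrow(runs) == 0) next

    if (!is.null(support)) {
      # boundary refinement on the support profile
      for (r in seq_len(nrow(runs))) {
        sup <- support[idx[runs$from[r]:runs$to[r]]]
        floor_sup <- 0.5 * median(sup[sup > 0])
        a <- runs$from[r]; b <- runs$to[r]
        while (a < b && support[idx[a]] < floor_sup) a <- a + 1
        while (b > a && support[idx[b]] < floor_sup) b <- b - 1
        runs$from[r] <- a; runs$to[r] <- b
      }
    }

    mean_vec <- function(a, b) {
      sub <- cn[, idx[a:b], drop = FALSE]
      rowMeans(sub, na.rm = TRUE)
    }
    # left-to-right correlation merge of neighboring intervals
    merged <- runs[1, , drop = FALSE]
    for (r in seq_len(nrow(runs))[-1]) {
      last <- nrow(merged)
      gap <- runs$from[r] - merged$to[last] - 1
      do_merge <- FALSE
      if (gap <= cfg$merge_dist_windows) {
        v1 <- mean_vec(merged$from[last], merged$to[last])
        v2 <- mean_vec(runs$from[r], runs$to[r])
        if (stats::sd(v1) > 0 && stats::sd(v2) > 0) {
          do_merge <- cor(v1, v2) >= cfg$corr_min
        }
      }
      if (do_merge) {
        merged$to[last] <- runs$to[r]
      } else {
        merged <- rbind(merged, runs[r, ])
      }
    }
    for (r in seq_len(nrow(merged))) {
      gidx <- idx[c(merged$from[r], merged$to[r])]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = w$start[gidx[1]], end = w$end[gidx[2]],
        first_window = gidx[1], last_window = gidx[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), first_window = integer(0),
                      last_window = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Genotype one CNVR interval
#'
#' Per sample, the real copy number is the median over the interval's
#' unmasked windows; the integer copy number rounds half away from zero and
#' is floored at 0.
#'
#' @param cn samples x windows copy number matrix.
#' @param genome the matching `windowed_genome`.
#' @param first_window,last_window window index range of the interval.
#' @return list with numeric vectors `real` and integer `int`, named by
#'   sample.
#' @export
genotype_cnvr <- function(cn, genome, first_window, last_window) {
  idx <- first_window:last_window
  idx <- idx[!genome$windows$masked[idx]]
  if (length(idx) == 0)
    stop("annotation error: interval is fully masked")
  real <- apply(cn[, idx, drop = FALSE], 1, median, na.rm = TRUE)
  int <- pmax(0, round_half_up(real))
  list(real = real, int = as.integer(int))
}

#' Loss and gain allele frequencies of a CNVR
#'
#' In `carrier` mode (default) the loss (gain) frequency is the fraction of
#' samples with integer copy number below (above) 2. In `allele` mode each
#' sample contributes `min(2, max(0, 2 - cn))` loss alleles and
#' `min(2, max(0, cn - 2))` gain alleles out of 2.
#'
#' @param cn_int integer copy numbers, one per sample.
#' @param mode "carrier" or "allele".
#' @return named numeric vector `c(loss_af=, gain_af=)`.
#' @export
allele_frequencies <- function(cn_int, mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  if (length(cn_int) == 0) stop("input error: no samples")
  if (mode == "carrier") {
    c(loss_af = mean(cn_int < 2), gain_af = mean(cn_int > 2))
  } else {
    loss <- pmin(2, pmax(0, 2 - cn_int))
    gain <- pmin(2, pmax(0, cn_int - 2))
    c(loss_af = sum(loss) / (2 * length(cn_int)),
      gain_af = sum(gain) / (2 * length(cn_int)))
  }
}

#' Classify a CNVR from its loss and gain allele frequencies
#'
#' Loss: `0.05 < loss_af <= 0.95` and `gain_af <= 0.01`.
#' Gain: `0.05 < gain_af < 0.95` and `loss_af <= 0.01`.
#' Both: `0.05 < gain_af < 0.95` and `0.05 < loss_af <= 0.95`.
#' Anything else is "none" (excluded by the final filter).
#'
#' @param loss_af,gain_af frequencies in `[0, 1]` (vectorized).
#' @return character vector in `c("loss", "gain", "both", "none")`.
#' @export
classify_cnvr <- function(loss_af, gain_af) {
  stopifnot(all(loss_af >= 0 & loss_af <= 1), all(gain_af >= 0 & gain_af <= 1))
  type <- rep("none", length(loss_af))
  type[loss_af > 0.05 & loss_af <= 0.95 & gain_af <= 0.01] <- "loss"
  type[gain_af > 0.05 & gain_af < 0.95 & loss_af <= 0.01] <- "gain"
  type[gain_af > 0.05 & gain_af < 0.95 & loss_af > 0.05 & loss_af <= 0.95] <- "both"
  type
}

#' Silhouette score of copy number genotypes
#'
#' Standard silhouette on the one-dimensional real copy numbers with
#' Euclidean distance, clusters defined by the integer copy number states.
#' Degenerate conventions: exactly one cluster scores 1.0; a singleton
#' cluster contributes 0 for its point; a point with zero distance to both
#' its own and the nearest other cluster contributes 0.
#'
#' @param real numeric per-sample copy numbers.
#' @param int integer per-sample copy states (cluster labels).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(real, int) {
  stopifnot(length(real) == length(int))
  if (length(real) < 2) stop("input error: need at least 2 samples")
  labs <- unique(int)
  if (length(labs) == 1) return(1.0)
  n <- length(real)
  d <- abs(outer(real, real, `-`))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(int == int[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, int[i]), function(l) {
      mean(d[i, int == l])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Filter CNVRs on type, silhouette and length
#'
#' Retains CNVRs whose type is not "none", whose silhouette strictly
#' exceeds `sil_min`, and whose length does not exceed the cap of their
#' type (loss and both: 50 kb; gain: 500 kb by default).
#'
#' @param cnvrs data.frame with columns `type`, `silhouette`, `length`.
#' @param sil_min silhouette threshold (default 0.6, strict).
#' @param loss_max_len,gain_max_len,both_max_len length caps in bp.
#' @return the retained rows.
#' @export
filter_cnvrs <- function(cnvrs, sil_min = 0.6, loss_max_len = 50000,
                         gain_max_len = 500000, both_max_len = 50000) {
  caps <- c(loss = loss_max_len, gain = gain_max_len, both = both_max_len)
  keep <- cnvrs$type != "none" &
    cnvrs$silhouette > sil_min &
    cnvrs$length <= unname(caps[cnvrs$type])
  keep[is.na(keep)] <- FALSE
  out <- cnvrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build, genotype, classify and filter population CNVRs
#'
#' The full aggregation stage: candidate windows -> interval merging ->
#' per-sample genotyping -> allele frequencies and type -> silhouette ->
#' filters.
#'
#' @inheritParams candidate_windows
#' @param af_mode frequency model passed to [allele_frequencies()].
#' @param filter apply [filter_cnvrs()] (default TRUE).
#' @param ... passed to [filter_cnvrs()].
#' @return list of class `cnvr_set`: `cnvrs` (data.frame `id`, `chrom`,
#'   `start`, `end`, `length`, `type`, `loss_af`, `gain_af`, `silhouette`,
#'   `n_samples`), `geno_real` and `geno_int` (CNVR x sample matrices).
#' @export
build_cnvrs <- function(cn, genome, calls = NULL, cfg = merge_config(),
                        af_mode = "carrier", filter = TRUE, ...) {
  flags <- candidate_windows(cn, genome, cfg, calls = calls)
  raw <- merge_to_cnvrs(flags, cn, genome, cfg)
  n <- nrow(raw)
  samples <- rownames(cn)
  geno_real <- matrix(NA_real_, n, length(samples),
                      dimnames = list(NULL, samples))
  geno_int <- matrix(NA_integer_, n, length(samples),
                     dimnames = list(NULL, samples))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genotype_cnvr(cn, genome, raw$first_window[i], raw$last_window[i])
    geno_real[i, ] <- g$real
    geno_int[i, ] <- g$int
    af <- allele_frequencies(g$int, mode = af_mode)
    rec[[i]] <- data.frame(
      id = region_id(raw$chrom[i], raw$start[i], raw$end[i]),
      chrom = raw$chrom[i], start = raw$start[i], end = raw$end[i],
      length = raw$end[i] - raw$start[i],
      type = classify_cnvr(af[["loss_af"]], af[["gain_af"]]),
      loss_af = af[["loss_af"]], gain_af = af[["gain_af"]],
      silhouette = silhouette_score(g$real, g$int),
      n_samples = length(samples), stringsAsFactors = FALSE)
  }
  cnvrs <- if (n) do.call(rbind, rec) else
    data.frame(id = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), length = numeric(0), type = character(0),
               loss_af = numeric(0), gain_af = numeric(0),
               silhouette = numeric(0), n_samples = integer(0),
               stringsAsFactors = FALSE)
  rownames(geno_real) <- rownames(geno_int) <- cnvrs$id
  if (filter && n) {
    cnvrs <- filter_cnvrs(cnvrs, ...)
    geno_real <- geno_real[cnvrs$id, , drop = FALSE]
    geno_int <- geno_int[cnvrs$id, , drop = FALSE]
  }
  structure(list(cnvrs = cnvrs, geno_real = geno_real, geno_int = geno_int),
            class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d CNVRs (%s)\n", nrow(x$cnvrs),
              paste(names(table(x$cnvrs$type)), table(x$cnvrs$type),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
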