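#' Default planted-region specifications for a five-group cohort
#'
#' Builds the stock truth layout used by the demo cohorts: six
#' population-stratified loci modeled on classic breed-differential CNV
#' patterns (a deletion fixed in one local breed and absent elsewhere; a
#' duplication fixed in one breed but at 50% in the commercial reference
#' breeds; a deletion at 95% vs 5%; a 55% deletion; a high-frequency CN4
#' duplication private to one breed; a low-frequency deletion shared with
#' the references) plus `n_shared` regions with equal carrier frequency in
#' every group (undifferentiated background). One region per local-breed
#' contrast is marked `differential = TRUE`: the locus designed to carry an
#' extreme between-group contrast (focal-private fixed deletion, 0.95-vs-0.05
#' deletion, 0.7 CN4 duplication), so exactly one candidate is expected per
#' contrast in a top-quantile scan.
#'
#' Regions are 5-8 windows long and spread evenly across chromosomes with
#' wide spacing so they never interact during merging.
#'
#' @param genome a `windowed_genome`.
#' @param groups character vector of five group labels; the first three are
#'   treated as local breeds, the last two as the pooled reference.
#' @param n_shared number of equal-frequency background regions (default 14).
#' @return a region-spec data.frame suitable for [plant_truth()].
#' @export
default_region_specs <- function(genome,
                                 groups = c("RC", "T", "WZS", "YL", "LR"),
                                 n_shared = 14) {
  stopifnot(length(groups) == 5)
  loc <- groups[1:3]; ref <- groups[4:5]
  f <- function(...) {
    v <- c(...)
    out <- setNames(rep(0, 5), groups)
    out[names(v)] <- v
    out
  }
  pat <- list(
    list(kind = "loss", cn = 0, diff = TRUE,
         freq = f(setNames(1.0, loc[1]))),
    list(kind = "gain", cn = 3, diff = FALSE,
         freq = f(setNames(c(1.0, 0.5, 0.5), c(loc[1], ref)))),
    list(kind = "loss", cn = 1, diff = TRUE,
         freq = f(setNames(c(0.95, 0.05, 0.05), c(loc[2], ref)))),
    list(kind = "loss", cn = 1, diff = FALSE,
         freq = f(setNames(c(0.55, 0.05, 0.05), c(loc[2], ref)))),
    list(kind = "gain", cn = 4, diff = TRUE,
         freq = f(setNames(0.7, loc[3]))),
    list(kind = "loss", cn = 1, diff = FALSE,
         freq = f(setNames(c(0.15, 0.35, 0.35), c(loc[3], ref))))
  )
  shared_kind <- rep(c("loss", "gain"), length.out = n_shared)
  shared_cn <- rep(c(1, 3, 0, 4), length.out = n_shared)
  shared_cn <- ifelse(shared_kind == "gain",
                      ifelse(shared_cn %in% c(3, 4), shared_cn, 3),
                      ifelse(shared_cn %in% c(0, 1), shared_cn, 1))
  shared_freq <- rep(c(0.3, 0.5, 0.2, 0.25, 0.6, 0.4, 0.2), length.out = n_shared)
  for (i in seq_len(n_shared)) {
    pat[[length(pat) + 1]] <- list(kind = shared_kind[i], cn = shared_cn[i],
                                   diff = FALSE,
                                   freq = setNames(rep(shared_freq[i], 5), groups))
  }

  n_regions <- length(pat)
  chroms <- names(genome$chrom_lengths)
  # regions distributed proportionally to chromosome length
  # (largest-remainder rounding), as in real CNVR maps
  share <- n_regions * genome$chrom_lengths / sum(genome$chrom_lengths)
  per_chrom <- floor(share)
  rem <- n_regions - sum(per_chrom)
  if (rem > 0) {
    extra <- order(share - floor(share), decreasing = TRUE)[seq_len(rem)]
    per_chrom[extra] <- per_chrom[extra] + 1
  }
  # 6.4-11.2 kb regions: the lower half of a realistic CNV size
  # distribution, and long enough that per-sample region medians are
  # essentially noise-free at default coverage
  lens <- rep(c(8L, 10L, 12L, 14L), length.out = n_regions)  # windows

  specs <- vector("list", n_regions)
  k <- 0
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    nw <- sum(genome$windows$chrom == chrom)
    m <- per_chrom[[chrom]]
    if (m == 0) next
    anchors <- floor(seq(0.08, 0.88, length.out = m) * nw)
    w <- genome$windows[genome$windows$chrom == chrom, ]
    for (j in seq_len(m)) {
      k <- k + 1
      a <- anchors[j] + 1
      b <- min(a + lens[k] - 1, nrow(w))
      p <- pat[[k]]
      specs[[k]] <- data.frame(
        chrom = chrom, start = w$start[a], end = w$end[b],
        kind = p$kind, carrier_cn = p$cn, differential = p$diff,
        as.list(setNames(p$freq, paste0("freq_", names(p$freq)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  out
}

#' Simulate the reference study-scale cohort
#'
#' One call producing every input of the pipeline at the scale used
#' throughout the package's own validation: five groups of ten diploid
#' samples, four unequal chromosomes totaling 2 Mb tiled into 800 bp
#' windows (2500 windows), 20 planted regions
#' ([default_region_specs()]), 50 expected
#' reads per window with quadratic GC bias and mild negative binomial
#' overdispersion, plus synthetic gene/QTL annotation.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param group_size samples per group (default 10).
#' @param chrom_lengths named vector of chromosome lengths; the default
#'   four unequal autosome-like chromosomes total 2 Mb (2500 windows).
#' @param mean_coverage expected reads/window (default 50).
#' @param dispersion negative binomial overdispersion (default 0.003).
#' @return list with `genome`, `truth`, `depth`, `annotation`, and the
#'   `groups` data.frame.
#' @export
simulate_study_cohort <- function(seed = 1L, group_size = 10,
                                  chrom_lengths = c(chr1 = 720000,
                                                    chr2 = 560000,
                                                    chr3 = 440000,
                                                    chr4 = 280000),
                                  mean_coverage = 50, dispersion = 0.003) {
  genome <- make_windowed_genome(chrom_lengths, window_size = 800,
                                 gc_profile_seed = derive_seed(seed, "genome"))
  group_sizes <- setNames(rep(group_size, 5), c("RC", "T", "WZS", "YL", "LR"))
  specs <- default_region_specs(genome)
  truth <- plant_truth(genome, group_sizes, specs,
                       seed = derive_seed(seed, "truth"))
  depth <- simulate_depth(genome, truth, mean_coverage = mean_coverage,
                          dispersion = dispersion,
                          seed = derive_seed(seed, "depth"))
  annotation <- emit_annotations(genome, n_genes = 40, exons_per_gene = 3,
                                 n_qtls = 15,
                                 seed = derive_seed(seed, "annotation"))
  list(genome = genome, truth = truth, depth = depth,
       annotation = annotation, groups = truth$sample_groups)
}
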