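#' Plant population-stratified copy number truth into a cohort
#'
#' Creates the ground-truth regions and per-sample integer copy numbers for a
#' synthetic multi-population diploid cohort. Each region spec requests a
#' per-group carrier frequency; carriers are drawn without replacement within
#' each group so the realized carrier count equals `round(freq * n)` exactly
#' (half rounded up). Gains assign copy number 3 or 4 to carriers, losses 1
#' or 0; non-carriers stay at the diploid state 2.
#'
#' @param genome a `windowed_genome`.
#' @param group_sizes named integer vector, group label -> number of samples.
#' @param region_specs a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, aligned to window boundaries), `kind` ("gain" or
#'   "loss"), optional `carrier_cn` (gain: 3 or 4, loss: 0 or 1; defaults 3
#'   and 1), optional `differential` (logical; marks the designated
#'   strongly-stratified locus of a contrast), plus one `freq_<group>` column
#'   per group with the requested carrier frequency (missing/NA treated as 0).
#' @param seed integer seed for carrier sampling.
#' @return An object of class `cnv_truth`: list with `regions` (the validated
#'   spec plus `region_id` and realized per-group carrier counts),
#'   `carriers` (data.frame `region_id`, `sample`, `cn`), and
#'   `sample_groups` (data.frame `sample`, `group`).
#' @export
plant_truth <- function(genome, group_sizes, region_specs, seed = 1L) {
  stopifnot(is.data.frame(region_specs))
  if (is.null(names(group_sizes)) || any(group_sizes < 1))
    stop("group_sizes must be a named vector of positive counts")
  groups <- names(group_sizes)
  sample_groups <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sample = sprintf("%s_%02d", g, seq_len(group_sizes[[g]])),
               group = g, stringsAsFactors = FALSE)
  }))

  rs <- region_specs
  if (is.null(rs$carrier_cn))
    rs$carrier_cn <- rep(NA_real_, nrow(rs))
  rs$carrier_cn <- ifelse(is.na(rs$carrier_cn),
                          ifelse(rs$kind == "gain", 3, 1), rs$carrier_cn)
  if (is.null(rs$differential)) rs$differential <- rep(FALSE, nrow(rs))
  if (!all(rs$kind %in% c("gain", "loss")))
    stop("specification error: kind must be 'gain' or 'loss'")
  ok_cn <- ifelse(rs$kind == "gain", rs$carrier_cn %in% c(3, 4),
                  rs$carrier_cn %in% c(0, 1))
  if (!all(ok_cn))
    stop("specification error: gains take carrier CN 3 or 4, losses 0 or 1")

  freq_cols <- paste0("freq_", groups)
  for (fc in freq_cols) if (is.null(rs[[fc]])) rs[[fc]] <- rep(0, nrow(rs))
  fr <- as.matrix(rs[, freq_cols, drop = FALSE])
  fr[is.na(fr)] <- 0
  if (any(fr < 0 | fr > 1))
    stop("specification error: carrier frequencies must lie in [0, 1]")

  # Validate placement: on-genome, window-aligned, mutually non-overlapping.
  for (i in seq_len(nrow(rs)))
    interval_to_window_range(genome, rs$chrom[i], rs$start[i], rs$end[i])
  o <- order(rs$chrom, rs$start)
  so <- rs[o, ]
  if (nrow(so) > 1 &&
      any(so$chrom[-1] == so$chrom[-nrow(so)] & so$start[-1] < so$end[-nrow(so)]))
    stop("specification error: planted regions overlap")

  rs$region_id <- region_id(rs$chrom, rs$start, rs$end)

  set.seed(seed)
  carriers <- vector("list", nrow(rs))
  for (i in seq_len(nrow(rs))) {
    picked <- character(0)
    for (g in groups) {
      f <- fr[i, paste0("freq_", g)]
      n <- group_sizes[[g]]
      k <- round_half_up(f * n)
      if (k > 0) {
        members <- sample_groups$sample[sample_groups$group == g]
        picked <- c(picked, sample(members, k))
      }
      rs[[paste0("carriers_", g)]][i] <- k
    }
    carriers[[i]] <- if (length(picked))
      data.frame(region_id = rs$region_id[i], sample = picked,
                 cn = rs$carrier_cn[i], stringsAsFactors = FALSE)
    else NULL
  }
  carriers <- do.call(rbind, carriers)
  if (is.null(carriers))
    carriers <- data.frame(region_id = character(0), sample = character(0),
                           cn = numeric(0), stringsAsFactors = FALSE)

  structure(list(regions = rs, carriers = carriers,
                 sample_groups = sample_groups),
            class = "cnv_truth")
}

#' @export
print.cnv_truth <- function(x, ...) {
  cat(sprintf("cnv_truth: %d regions, %d samples in %d groups\n",
              nrow(x$regions), nrow(x$sample_groups),
              length(unique(x$sample_groups$group))))
  invisible(x)
}

# True integer CN matrix (samples x windows) implied by a truth set.
truth_cn_matrix <- function(genome, truth) {
  samples <- truth$sample_groups$sample
  cn <- matrix(2, nrow = length(samples), ncol = nrow(genome$windows),
               dimnames = list(samples, window_ids(genome)))
  for (i in seq_len(nrow(truth$regions))) {
    r <- truth$regions[i, ]
    idx <- interval_to_window_range(genome, r$chrom, r$start, r$end)
    rc <- truth$carriers[truth$carriers$region_id == r$region_id, ]
    if (nrow(rc)) cn[rc$sample, idx] <- rc$cn  # recycled column-major
  }
  cn
}

# Multiplicative GC bias curve: unimodal quadratic with configurable peak and
# strength, floored at 0.1 so expected depth never vanishes from bias alone.
gc_bias_curve <- function(gc, peak = 0.35, strength = 1.2) {
  pmax(0.1, 1 - strength * (gc - peak)^2)
}

#' Simulate a noisy read-depth matrix for a planted cohort
#'
#' Expected depth of a window is
#' `mean_coverage * (CN/2) * bias(gc)` where `bias` is a unimodal quadratic
#' in GC; counts are negative binomial with the given overdispersion
#' (Poisson as `dispersion` tends to 0; `var = mu + dispersion * mu^2`).
#' Masked windows receive erratic depth (a uniform 0-3x multiplier per cell)
#' and are excluded from every downstream statistic.
#'
#' @param genome a `windowed_genome`.
#' @param truth a `cnv_truth` (from [plant_truth()]).
#' @param mean_coverage expected reads per window for a diploid unbiased
#'   window (default 50, i.e. roughly 9.5x with 150 bp reads on 800 bp
#'   windows).
#' @param gc_bias numeric vector `c(peak=, strength=)` of the bias curve.
#' @param dispersion negative binomial overdispersion; `<= 0` means Poisson.
#' @param seed integer seed.
#' @return numeric matrix samples x windows, rownames sample ids, colnames
#'   window ids.
#' @export
simulate_depth <- function(genome, truth, mean_coverage = 50,
                           gc_bias = c(peak = 0.35, strength = 1.2),
                           dispersion = 0.003, seed = 1L) {
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  set.seed(seed)
  cn <- truth_cn_matrix(genome, truth)
  bias <- gc_bias_curve(genome$windows$gc, gc_bias[["peak"]],
                        gc_bias[["strength"]])
  mu <- sweep(cn / 2, 2, mean_coverage * bias, `*`)
  masked <- genome$windows$masked
  if (any(masked)) {
    n_cells <- nrow(mu) * sum(masked)
    mu[, masked] <- mean_coverage * runif(n_cells, 0, 3)
  }
  vals <- if (dispersion <= 0) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  depth <- matrix(as.numeric(vals), nrow = nrow(mu), dimnames = dimnames(mu))
  depth
}

#' Generate synthetic gene and QTL annotation fixtures
#'
#' Places non-overlapping gene bodies (each with internal exon
#' sub-intervals) and QTL intervals with trait labels on a windowed genome.
#' Coordinates are 0-based half-open and sorted.
#'
#' @param genome a `windowed_genome`.
#' @param n_genes,n_qtls numbers of features to place (>= 0).
#' @param exons_per_gene exon sub-intervals per gene.
#' @param seed integer seed.
#' @return list with data.frames `genes` (`chrom`, `start`, `end`,
#'   `gene_id`), `exons` (same + `gene_id`), `qtls` (`chrom`, `start`, `end`,
#'   `trait`).
#' @export
emit_annotations <- function(genome, n_genes, exons_per_gene = 3, n_qtls,
                             seed = 1L) {
  if (n_genes < 0 || n_qtls < 0 || exons_per_gene < 1)
    stop("specification error: feature counts must be non-negative")
  set.seed(seed)
  chroms <- names(genome$chrom_lengths)

  place_nonoverlapping <- function(n, min_len, max_len) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
    tries <- 0
    while (nrow(out) < n) {
      tries <- tries + 1
      if (tries > 200 * n + 200)
        stop("specification error: requested features cannot fit on the genome")
      chrom <- sample(chroms, 1)
      len <- round(runif(1, min_len, max_len))
      if (len >= genome$chrom_lengths[[chrom]]) next
      start <- floor(runif(1, 0, genome$chrom_lengths[[chrom]] - len))
      end <- start + len
      clash <- out$chrom == chrom & out$start < end & out$end > start
      if (!any(clash))
        out <- rbind(out, data.frame(chrom = chrom, start = start, end = end,
                                     stringsAsFactors = FALSE))
    }
    out[order(out$chrom, out$start), , drop = FALSE]
  }

  genes <- place_nonoverlapping(n_genes, 2 * genome$window_size,
                                8 * genome$window_size)
  if (n_genes > 0) {
    genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      len <- g$end - g$start
      # split the gene body into 2*k segments, odd segments are exons
      k <- exons_per_gene
      cuts <- round(seq(0, len, length.out = 2 * k + 1))
      data.frame(chrom = g$chrom,
                 start = g$start + cuts[seq(1, 2 * k, by = 2)],
                 end = g$start + cuts[seq(2, 2 * k + 1, by = 2)],
                 gene_id = g$gene_id, stringsAsFactors = FALSE)
    }))
  } else {
    genes <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
    exons <- genes
  }

  traits <- c("backfat_thickness", "meat_quality", "intramuscular_fat",
              "growth_rate", "litter_size", "immune_response")
  if (n_qtls > 0) {
    qtls <- place_nonoverlapping(n_qtls, 5 * genome$window_size,
                                 20 * genome$window_size)
    qtls$trait <- sample(traits, nrow(qtls), replace = TRUE)
  } else {
    qtls <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), trait = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(genes) <- rownames(exons) <- rownames(qtls) <- NULL
  list(genes = genes, exons = exons, qtls = qtls)
}
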