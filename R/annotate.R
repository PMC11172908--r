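#' Genomic context of each CNVR
#'
#' Labels each CNVR `exon` if it overlaps any exon by at least 1 bp, else
#' `intron` if it overlaps any gene body, else `intergenic` (precedence
#' exon > intron > intergenic). All coordinates 0-based half-open.
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end`.
#' @param annotation list with data.frames `genes` and `exons` (as from
#'   [emit_annotations()]).
#' @return character vector of labels, one per CNVR.
#' @export
genomic_context <- function(cnvrs, annotation) {
  n <- nrow(cnvrs)
  if (n == 0) return(character(0))
  labels <- rep("intergenic", n)
  gr <- intervals_to_granges(cnvrs)
  if (nrow(annotation$genes) > 0) {
    hits_gene <- GenomicRanges::countOverlaps(
      gr, intervals_to_granges(annotation$genes)) > 0
    labels[hits_gene] <- "intron"
  }
  if (nrow(annotation$exons) > 0) {
    hits_exon <- GenomicRanges::countOverlaps(
      gr, intervals_to_granges(annotation$exons)) > 0
    labels[hits_exon] <- "exon"
  }
  labels
}

#' Genes overlapped by CNVRs under the >= 50% rule
#'
#' A gene is assigned to a CNVR when the intersection covers at least
#' `min_gene_fraction` of the gene (fully contained genes always qualify).
#' The denominator can be switched to the CNVR length with
#' `denominator = "cnvr"`.
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end` and (optionally)
#'   `id`.
#' @param annotation list with a `genes` data.frame (`chrom`, `start`,
#'   `end`, `gene_id`).
#' @param min_gene_fraction overlap fraction threshold (default 0.5,
#'   inclusive).
#' @param denominator "gene" (default) or "cnvr".
#' @return data.frame `cnvr_id`, `gene_id`, `overlap_bp`, `fraction`.
#' @export
overlap_genes <- function(cnvrs, annotation, min_gene_fraction = 0.5,
                          denominator = c("gene", "cnvr")) {
  denominator <- match.arg(denominator)
  empty <- data.frame(cnvr_id = character(0), gene_id = character(0),
                      overlap_bp = numeric(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(cnvrs) == 0 || nrow(annotation$genes) == 0) return(empty)
  ids <- if (!is.null(cnvrs$id)) cnvrs$id else
    region_id(cnvrs$chrom, cnvrs$start, cnvrs$end)
  gr_c <- intervals_to_granges(cnvrs)
  gr_g <- intervals_to_granges(annotation$genes)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g)
  if (length(hits) == 0) return(empty)
  qi <- queryHits(hits); si <- subjectHits(hits)
  inter <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr_c)[qi], GenomicRanges::ranges(gr_g)[si]))
  denom <- if (denominator == "gene")
    annotation$genes$end[si] - annotation$genes$start[si]
  else cnvrs$end[qi] - cnvrs$start[qi]
  frac <- inter / denom
  keep <- frac >= min_gene_fraction
  data.frame(cnvr_id = ids[qi][keep],
             gene_id = annotation$genes$gene_id[si][keep],
             overlap_bp = inter[keep], fraction = frac[keep],
             stringsAsFactors = FALSE)
}

#' QTL overlap of CNVRs (any-overlap semantics)
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end`, optional `id`.
#' @param qtls data.frame with `chrom`, `start`, `end`, `trait`.
#' @return list with `overlaps` (data.frame `cnvr_id`, `trait`),
#'   `n_cnvrs_with_qtl`, and `n_distinct_traits`.
#' @export
overlap_qtls <- function(cnvrs, qtls) {
  empty <- list(overlaps = data.frame(cnvr_id = character(0),
                                      trait = character(0),
                                      stringsAsFactors = FALSE),
                n_cnvrs_with_qtl = 0L, n_distinct_traits = 0L)
  if (nrow(cnvrs) == 0 || is.null(qtls) || nrow(qtls) == 0) return(empty)
  ids <- if (!is.null(cnvrs$id)) cnvrs$id else
    region_id(cnvrs$chrom, cnvrs$start, cnvrs$end)
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(cnvrs),
                                      intervals_to_granges(qtls))
  if (length(hits) == 0) return(empty)
  df <- unique(data.frame(cnvr_id = ids[queryHits(hits)],
                          trait = qtls$trait[subjectHits(hits)],
                          stringsAsFactors = FALSE))
  list(overlaps = df,
       n_cnvrs_with_qtl = length(unique(df$cnvr_id)),
       n_distinct_traits = length(unique(df$trait)))
}

#' CNVR counts per chromosome and the count-vs-length regression
#'
#' Ordinary least squares of per-chromosome CNVR count on chromosome
#' length. Requires at least three chromosomes; otherwise the regression is
#' skipped with a warning and the fit fields are `NA`.
#'
#' @param cnvrs data.frame with a `chrom` column.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return list with `per_chrom` (data.frame `chrom`, `cnvr_count`,
#'   `chrom_length`), `slope`, `intercept`, `r2`, `p_value`.
#' @export
chromosome_summary <- function(cnvrs, chrom_lengths) {
  counts <- table(factor(cnvrs$chrom, levels = names(chrom_lengths)))
  per_chrom <- data.frame(chrom = names(chrom_lengths),
                          cnvr_count = as.integer(counts),
                          chrom_length = as.numeric(chrom_lengths),
                          stringsAsFactors = FALSE)
  if (nrow(per_chrom) < 3) {
    warning("fewer than 3 chromosomes: count-vs-length regression skipped")
    return(list(per_chrom = per_chrom, slope = NA_real_,
                intercept = NA_real_, r2 = NA_real_, p_value = NA_real_))
  }
  fit <- lm(cnvr_count ~ chrom_length, data = per_chrom)
  sm <- suppressWarnings(summary(fit))
  p <- if (!is.null(sm$fstatistic) && is.finite(sm$fstatistic[1]))
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  else NA_real_
  list(per_chrom = per_chrom,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p_value = p)
}

#' Whole-set summary statistics for calls and CNVRs
#'
#' @param calls per-sample CNV calls (may be NULL).
#' @param cnvrs CNVR data.frame (may be NULL).
#' @param chrom_lengths named vector of chromosome lengths (for the genome
#'   coverage fraction; may be NULL).
#' @return list of totals: CNV count and per-kind counts, per-individual
#'   mean/min/max counts, call length median/mean, CNVR type counts, and
#'   the fraction of the genome covered by the union of CNVR intervals.
#' @export
summary_stats <- function(calls = NULL, cnvrs = NULL, chrom_lengths = NULL) {
  out <- list()
  if (!is.null(calls) && nrow(calls) > 0) {
    per_ind <- table(calls$sample)
    lens <- calls$end - calls$start
    out$total_cnvs <- nrow(calls)
    out$n_gain <- sum(calls$kind == "gain")
    out$n_loss <- sum(calls$kind == "loss")
    out$cnvs_per_individual_mean <- mean(per_ind)
    out$cnvs_per_individual_min <- min(per_ind)
    out$cnvs_per_individual_max <- max(per_ind)
    out$call_length_median <- median(lens)
    out$call_length_mean <- mean(lens)
  }
  if (!is.null(cnvrs) && nrow(cnvrs) > 0) {
    out$n_cnvrs <- nrow(cnvrs)
    out$cnvr_type_counts <- as.list(table(cnvrs$type))
    out$cnvr_length_median <- median(cnvrs$end - cnvrs$start)
    out$cnvr_length_mean <- mean(cnvrs$end - cnvrs$start)
    if (!is.null(chrom_lengths)) {
      merged <- GenomicRanges::reduce(intervals_to_granges(cnvrs))
      out$genome_coverage <- sum(IRanges::width(merged)) / sum(chrom_lengths)
    }
  }
  out
}

#' Overlap comparison with another CNVR study
#'
#' `overlap_number` counts this set's CNVRs that intersect at least one
#' interval of the other set; `overlap_ratio` divides by this set's size
#' (reported rounded to 2 decimals, the convention of cross-study CNVR
#' comparison tables); `overlap_length_mb` is the total intersection in Mb
#' after merging each set (no double counting).
#'
#' @param ours CNVR data.frame (`chrom`, `start`, `end`).
#' @param theirs interval data.frame (`chrom`, `start`, `end`).
#' @param label name of the other study.
#' @return data.frame with one row: `other_study_label`, `n_ours`,
#'   `n_theirs`, `overlap_number`, `overlap_ratio`, `overlap_length_mb`.
#' @export
compare_study <- function(ours, theirs, label = "other") {
  n_ours <- nrow(ours); n_theirs <- nrow(theirs)
  if (n_ours == 0 || n_theirs == 0) {
    return(data.frame(other_study_label = label, n_ours = n_ours,
                      n_theirs = n_theirs, overlap_number = 0L,
                      overlap_ratio = 0, overlap_length_mb = 0,
                      stringsAsFactors = FALSE))
  }
  lvls <- union(unique(ours$chrom), unique(theirs$chrom))
  gr_o <- intervals_to_granges(ours)
  gr_t <- intervals_to_granges(theirs)
  GenomeInfoDb::seqlevels(gr_o) <- lvls
  GenomeInfoDb::seqlevels(gr_t) <- lvls
  n_overlap <- sum(GenomicRanges::countOverlaps(gr_o, gr_t) > 0)
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(gr_o),
                                    GenomicRanges::reduce(gr_t))
  data.frame(other_study_label = label, n_ours = n_ours,
             n_theirs = n_theirs, overlap_number = n_overlap,
             overlap_ratio = round(n_overlap / n_ours, 2),
             overlap_length_mb = sum(IRanges::width(inter)) / 1e6,
             stringsAsFactors = FALSE)
}
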