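reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  inter <- inter * (chrom_a == chrom_b)
  pmin(inter / (end_a - start_a), inter / (end_b - start_b))
}

#' Compare detected CNVRs against planted truth
#'
#' Matches each planted region to the detected CNVR with the highest
#' reciprocal overlap and summarizes recovery and genotyping accuracy: the
#' fraction of planted regions recovered at `min_ro`, and the largest
#' absolute error between the estimated per-group carrier fraction and the
#' realized (planted) one across all matched regions and groups.
#'
#' @param truth a `cnv_truth`.
#' @param cnvr_set a `cnvr_set` from [build_cnvrs()].
#' @param min_ro reciprocal overlap required to count a region as
#'   recovered (default 0.8).
#' @return list with `matches` (per-region data.frame: `region_id`,
#'   `cnvr_id`, `ro`, `recovered`), `recovery` (fraction), and
#'   `max_carrier_freq_error`.
#' @export
evaluate_recovery <- function(truth, cnvr_set, min_ro = 0.8) {
  regions <- truth$regions
  cnvrs <- cnvr_set$cnvrs
  groups <- unique(truth$sample_groups$group)
  rows <- vector("list", nrow(regions))
  max_err <- 0
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ro <- if (nrow(cnvrs)) reciprocal_overlap(
      r$chrom, r$start, r$end, cnvrs$chrom, cnvrs$start, cnvrs$end) else 0
    best <- if (length(ro) && max(ro) > 0) which.max(ro) else NA_integer_
    ro_best <- if (is.na(best)) 0 else ro[best]
    rows[[i]] <- data.frame(
      region_id = r$region_id,
      cnvr_id = if (is.na(best)) NA_character_ else cnvrs$id[best],
      ro = ro_best, recovered = ro_best >= min_ro,
      stringsAsFactors = FALSE)
    if (!is.na(best) && ro_best >= min_ro) {
      gi <- cnvr_set$geno_int[cnvrs$id[best], ]
      for (g in groups) {
        mem <- truth$sample_groups$sample[truth$sample_groups$group == g]
        est <- if (r$kind == "loss") mean(gi[mem] < 2) else mean(gi[mem] > 2)
        realized <- r[[paste0("carriers_", g)]] / length(mem)
        max_err <- max(max_err, abs(est - realized))
      }
    }
  }
  matches <- do.call(rbind, rows)
  list(matches = matches, recovery = mean(matches$recovered),
       max_carrier_freq_error = max_err)
}

#' Check that designated differential loci are scan candidates
#'
#' For every planted region marked `differential`, tests whether some
#' candidate-flagged CNVR in the Vst scan overlaps it reciprocally at
#' `min_ro`.
#'
#' @param truth a `cnv_truth` whose regions carry a `differential` flag.
#' @param records a [vst_scan()] result.
#' @param min_ro reciprocal overlap threshold (default 0.8).
#' @return list with `n_differential`, `n_flagged`, and the per-region
#'   logical `flagged`.
#' @export
evaluate_scan <- function(truth, records, min_ro = 0.8) {
  diffr <- truth$regions[truth$regions$differential, , drop = FALSE]
  cand <- records[records$candidate, , drop = FALSE]
  flagged <- vapply(seq_len(nrow(diffr)), function(i) {
    if (nrow(cand) == 0) return(FALSE)
    cr <- parse_region_id(cand$cnvr_id)
    any(reciprocal_overlap(diffr$chrom[i], diffr$start[i], diffr$end[i],
                           cr$chrom, cr$start, cr$end) >= min_ro)
  }, logical(1))
  list(n_differential = nrow(diffr), n_flagged = sum(flagged),
       flagged = flagged)
}
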