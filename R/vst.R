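pop_var <- function(x) mean((x - mean(x))^2)

#' Vst differentiation statistic for one region and two groups
#'
#' `Vst = (Vt - Vs) / Vt` where `Vt` is the total variance of copy number
#' across the pooled samples and `Vs` the size-weighted mean of the
#' within-group variances (population variances, i.e. divided by n). With
#' variances the law of total variance bounds the statistic in `[0, 1]`.
#' `Vt == 0` returns 0 by convention. A standard-deviation variant
#' (`stat = "sd"`) is exposed for exploration but is not the default
#' because it loses the `[0, 1]` guarantee.
#'
#' @param values_a,values_b real copy numbers of the two groups (non-empty).
#' @param stat "variance" (default) or "sd".
#' @return the statistic (scalar).
#' @export
vst <- function(values_a, values_b, stat = c("variance", "sd")) {
  stat <- match.arg(stat)
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("input error: both groups must be non-empty")
  f <- if (stat == "variance") pop_var else function(x) sqrt(pop_var(x))
  vt <- f(c(values_a, values_b))
  if (vt == 0) return(0)
  na <- length(values_a); nb <- length(values_b)
  vs <- (na * f(values_a) + nb * f(values_b)) / (na + nb)
  (vt - vs) / vt
}

#' Scan all CNVRs for population differentiation
#'
#' Computes Vst per CNVR for each contrast (a focal group against a pooled
#' set of reference groups), using the real-valued genotypes. Records carry
#' the empirical percentile of their Vst within the contrast and, after
#' [top_candidates()], the candidate flag.
#'
#' @param geno_real CNVR x sample matrix of real copy numbers.
#' @param sample_groups data.frame `sample`, `group` covering every column.
#' @param contrasts list of `list(focal = "RC", ref = c("YL", "LR"))`
#'   entries; focal and reference groups must be disjoint.
#' @param q tail fraction for candidate flagging (default 0.05).
#' @param stat passed to [vst()].
#' @return data.frame `cnvr_id`, `contrast`, `vt`, `vs`, `vst`, `rank_pct`,
#'   `candidate`.
#' @export
vst_scan <- function(geno_real, sample_groups, contrasts, q = 0.05,
                     stat = "variance") {
  stopifnot(is.matrix(geno_real))
  miss <- setdiff(colnames(geno_real), sample_groups$sample)
  if (length(miss))
    stop("configuration error: samples without group assignment: ",
         paste(miss, collapse = ", "))
  grp <- setNames(sample_groups$group, sample_groups$sample)
  known <- unique(sample_groups$group)
  out <- list()
  for (ct in contrasts) {
    bad <- setdiff(c(ct$focal, ct$ref), known)
    if (length(bad))
      stop("configuration error: unknown group(s) in contrast: ",
           paste(bad, collapse = ", "))
    if (length(intersect(ct$focal, ct$ref)))
      stop("configuration error: contrast groups must be disjoint")
    label <- paste0(paste(ct$focal, collapse = "+"), "_vs_",
                    paste(ct$ref, collapse = "+"))
    a_cols <- colnames(geno_real)[grp[colnames(geno_real)] %in% ct$focal]
    b_cols <- colnames(geno_real)[grp[colnames(geno_real)] %in% ct$ref]
    recs <- lapply(seq_len(nrow(geno_real)), function(i) {
      va <- geno_real[i, a_cols]; vb <- geno_real[i, b_cols]
      pooled <- c(va, vb)
      f <- if (stat == "variance") pop_var else function(x) sqrt(pop_var(x))
      vt <- f(pooled)
      vs <- (length(va) * f(va) + length(vb) * f(vb)) / length(pooled)
      data.frame(cnvr_id = rownames(geno_real)[i], contrast = label,
                 vt = vt, vs = vs,
                 vst = if (vt == 0) 0 else (vt - vs) / vt,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    df$rank_pct <- 100 * rank(df$vst, ties.method = "average") / nrow(df)
    out[[label]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  top_candidates(res, q = q)
}

#' Flag the empirical top tail of a Vst scan
#'
#' Within each contrast, records whose Vst is strictly greater than the
#' `1 - q` empirical quantile (linear interpolation) are flagged; ties at
#' the threshold are excluded, so a degenerate contrast where every Vst is
#' equal flags nothing.
#'
#' @param records data.frame from [vst_scan()] (columns `contrast`, `vst`).
#' @param q tail fraction in (0, 1), default 0.05.
#' @return `records` with a logical `candidate` column.
#' @export
top_candidates <- function(records, q = 0.05) {
  if (!(q > 0 && q < 1)) stop("configuration error: q must be in (0, 1)")
  records$candidate <- FALSE
  for (label in unique(records$contrast)) {
    sel <- records$contrast == label
    thr <- quantile(records$vst[sel], 1 - q, type = 7, names = FALSE)
    records$candidate[sel] <- records$vst[sel] > thr
  }
  records
}

#' Per-group loss / normal / gain frequency panel
#'
#' For each CNVR and group, the fractions of samples with integer copy
#' number below, at, and above the diploid state — the tabular form of the
#' per-locus allele frequency panels used to display stratified loci.
#'
#' @param geno_int CNVR x sample matrix of integer copy numbers.
#' @param sample_groups data.frame `sample`, `group`.
#' @return data.frame `cnvr_id`, `group`, `loss_fraction`,
#'   `normal_fraction`, `gain_fraction` (rows sum to 1 per group).
#' @export
group_frequency_panel <- function(geno_int, sample_groups) {
  stopifnot(is.matrix(geno_int))
  miss <- setdiff(sample_groups$sample, colnames(geno_int))
  if (length(miss))
    stop("input error: missing genotypes for sample(s): ",
         paste(miss, collapse = ", "))
  if (any(is.na(geno_int[, sample_groups$sample])))
    stop("input error: NA genotype for a group member")
  out <- list()
  for (g in unique(sample_groups$group)) {
    cols <- sample_groups$sample[sample_groups$group == g]
    sub <- geno_int[, cols, drop = FALSE]
    out[[g]] <- data.frame(
      cnvr_id = rownames(geno_int), group = g,
      loss_fraction = rowMeans(sub < 2),
      normal_fraction = rowMeans(sub == 2),
      gain_fraction = rowMeans(sub > 2),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
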