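# Brute-force oracles, independent of the package implementation.

# Population variance by explicit summation.
bf_pop_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

bf_vst <- function(a, b) {
  vt <- bf_pop_var(c(a, b))
  if (vt == 0) return(0)
  vs <- (length(a) * bf_pop_var(a) + length(b) * bf_pop_var(b)) /
    (length(a) + length(b))
  (vt - vs) / vt
}

# Silhouette by definition, point by point, with the same degenerate
# conventions (one cluster -> 1, singleton -> 0, all-zero distances -> 0).
bf_silhouette <- function(real, int) {
  if (length(unique(int)) == 1) return(1)
  n <- length(real)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(int == int[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(abs(real[same] - real[i]))
    b <- Inf
    for (l in unique(int)) {
      if (l == int[i]) next
      b <- min(b, mean(abs(real[int == l] - real[i])))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# All-pairs interval intersection length (0-based half-open).
bf_inter_len <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  max(0, min(e1, e2) - max(s1, s2))
}

# Random interval set on a couple of chromosomes.
random_intervals <- function(n, max_pos = 1e5, max_len = 5e3,
                             chroms = c("chrA", "chrB")) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + ceiling(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}

# A small genome with hand-set GC and no masking, for constructed examples.
manual_genome <- function(n_windows, window_size = 100, gc = 0.5,
                          chrom = "chr1", masked = FALSE) {
  starts <- (seq_len(n_windows) - 1) * window_size
  structure(list(
    windows = data.frame(chrom = chrom, start = starts,
                         end = starts + window_size,
                         gc = rep_len(gc, n_windows),
                         masked = rep_len(masked, n_windows),
                         stringsAsFactors = FALSE),
    window_size = window_size,
    chrom_lengths = setNames(n_windows * window_size, chrom)),
    class = "windowed_genome")
}

# samples x windows matrix with dimnames matching a genome.
cn_matrix <- function(genome, rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- with(genome$windows,
                      sprintf("%s:%d-%d", chrom, start + 1, end))
  m
}
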