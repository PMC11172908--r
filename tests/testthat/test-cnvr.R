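test_that("candidate windows follow the population deviation-frequency rule", {
  g <- manual_genome(4, gc = 0.5)
  rows <- lapply(1:50, function(i) rep(2, 4))
  names(rows) <- sprintf("s%02d", 1:50)
  cn <- cn_matrix(g, rows)
  cfg <- merge_config(min_variant_freq = 0.05)
  expect_false(any(candidate_windows(cn, g, cfg)))

  cn3 <- cn; cn3[1:3, 2] <- 1       # 3/50 = 0.06 > 0.05 -> flagged
  cn2 <- cn; cn2[1:2, 2] <- 1       # 2/50 = 0.04       -> not flagged
  expect_true(candidate_windows(cn3, g, cfg)[2])
  expect_false(candidate_windows(cn2, g, cfg)[2])
  # support counts travel with the flags
  expect_equal(unname(attr(candidate_windows(cn3, g, cfg), "support")[2]), 3)
})

test_that("call-informed evidence ignores short calls and NA windows", {
  g <- manual_genome(8, gc = 0.5)
  rows <- lapply(1:10, function(i) rep(2, 8))
  names(rows) <- sprintf("s%02d", 1:10)
  cn <- cn_matrix(g, rows)
  cn[1:5, 3:6] <- 1
  calls <- data.frame(sample = sprintf("s%02d", 1:5), chrom = "chr1",
                      start = g$windows$start[3], end = g$windows$end[6],
                      kind = "loss", mean_cn = 1, n_windows = 4L,
                      stringsAsFactors = FALSE)
  cfg <- merge_config(min_variant_freq = 0.1, min_call_windows = 3)
  flags <- candidate_windows(cn, g, cfg, calls = calls)
  expect_equal(as.integer(which(flags)), 3:6)
  # the same deviations without any qualifying call leave nothing flagged
  short <- transform(calls, n_windows = 2L)
  expect_false(any(candidate_windows(cn, g, cfg, calls = short)))
})

test_that("interval merging honors correlation between neighbors", {
  g <- manual_genome(10, gc = 0.5)
  rows <- list(a = rep(2, 10), b = rep(2, 10), c = rep(2, 10), d = rep(2, 10))
  cn <- cn_matrix(g, rows)
  # two runs (windows 2:3 and 6:7) with identical per-sample patterns
  cn[c(1, 2), c(2, 3, 6, 7)] <- 1
  flags <- rep(FALSE, 10); flags[c(2, 3, 6, 7)] <- TRUE
  cfg <- merge_config(corr_min = 0.5, max_gap_windows = 1,
                      merge_dist_windows = 3)
  merged <- merge_to_cnvrs(flags, cn, g, cfg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$first_window, 2)
  expect_equal(merged$last_window, 7)

  # anticorrelated neighbors stay apart
  cn2 <- cn_matrix(g, rows)
  cn2[c(1, 2), c(2, 3)] <- 1
  cn2[c(3, 4), c(6, 7)] <- 1
  split <- merge_to_cnvrs(flags, cn2, g, cfg)
  expect_equal(nrow(split), 2)

  # a single run spans exactly its flagged windows
  one <- rep(FALSE, 10); one[4:6] <- TRUE
  res <- merge_to_cnvrs(one, cn, g, cfg)
  expect_equal(c(res$first_window, res$last_window), c(4, 6))
})

test_that("boundary refinement trims weakly supported edge windows", {
  g <- manual_genome(10, gc = 0.5)
  rows <- lapply(1:20, function(i) rep(2, 10))
  names(rows) <- sprintf("s%02d", 1:20)
  cn <- cn_matrix(g, rows)
  cn[1:10, 4:6] <- 1   # strong core, support 10
  cn[1:2, 3] <- 1      # weak edge, support 2
  flags <- rep(FALSE, 10); flags[3:6] <- TRUE
  support <- c(0, 0, 2, 10, 10, 10, 0, 0, 0, 0)
  attr(flags, "support") <- support
  trimmed <- merge_to_cnvrs(flags, cn, g, merge_config())
  expect_equal(c(trimmed$first_window, trimmed$last_window), c(4, 6))
  # without support information the full flagged run is kept
  plain <- flags; attr(plain, "support") <- NULL
  kept <- merge_to_cnvrs(plain, cn, g, merge_config())
  expect_equal(c(kept$first_window, kept$last_window), c(3, 6))
})

test_that("genotyping takes the median and rounds half away from zero", {
  g <- manual_genome(3, gc = 0.5)
  cn <- cn_matrix(g, list(s1 = c(1.1, 0.9, 1.0), s2 = c(2, 2, 2),
                          s3 = c(3.6, 3.4, 4.1)))
  geno <- genotype_cnvr(cn, g, 1, 3)
  expect_equal(unname(geno$real), c(1.0, 2.0, 3.6))
  expect_equal(unname(geno$int), c(1L, 2L, 4L))   # 3.6 rounds up to 4

  gm <- manual_genome(3, gc = 0.5, masked = TRUE)
  expect_error(genotype_cnvr(cn, gm, 1, 3), "masked")
})

test_that("allele frequencies match counting in both modes", {
  all_diploid <- rep(2L, 25)
  expect_equal(unname(allele_frequencies(all_diploid)), c(0, 0))

  one_null <- c(0L, rep(2L, 9))   # one homozygous deletion among 10
  expect_equal(allele_frequencies(one_null, mode = "allele")[["loss_af"]],
               2 / 20)
  expect_equal(allele_frequencies(one_null, mode = "carrier")[["loss_af"]],
               0.1)

  half_dup <- c(rep(3L, 10), rep(2L, 10))  # 10 of 20 carry a duplication
  expect_equal(allele_frequencies(half_dup, mode = "carrier")[["gain_af"]],
               0.5)
  expect_error(allele_frequencies(integer(0)), "no samples")
})

test_that("type classification matches the frequency predicates", {
  expect_equal(classify_cnvr(0.50, 0.00), "loss")
  expect_equal(classify_cnvr(0.00, 0.50), "gain")
  expect_equal(classify_cnvr(0.20, 0.20), "both")
  expect_equal(classify_cnvr(0.05, 0.00), "none")  # strict lower bound
  expect_equal(classify_cnvr(0.95, 0.00), "loss")  # inclusive upper bound
  expect_equal(classify_cnvr(0.00, 0.95), "none")  # strict gain upper bound
  expect_equal(classify_cnvr(0.50, 0.01), "loss")  # tolerated other-type AF
  expect_equal(classify_cnvr(0.50, 0.02), "none")
})

test_that("every classified CNVR satisfies exactly one predicate", {
  af <- expand.grid(loss = seq(0, 1, by = 0.05), gain = seq(0, 1, by = 0.05))
  type <- classify_cnvr(af$loss, af$gain)
  is_loss <- af$loss > 0.05 & af$loss <= 0.95 & af$gain <= 0.01
  is_gain <- af$gain > 0.05 & af$gain < 0.95 & af$loss <= 0.01
  is_both <- af$gain > 0.05 & af$gain < 0.95 & af$loss > 0.05 & af$loss <= 0.95
  expect_true(all(is_loss + is_gain + is_both <= 1))
  expect_equal(type == "none", !(is_loss | is_gain | is_both))
})

test_that("silhouette matches a brute-force computation", {
  expect_equal(silhouette_score(c(1, 1, 3, 3), c(1L, 1L, 3L, 3L)), 1.0)
  expect_equal(silhouette_score(c(2, 2, 2), c(2L, 2L, 2L)), 1.0)
  expect_equal(silhouette_score(c(1.9, 2.0, 2.1, 2.2), rep(2L, 4)), 1.0)
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    real <- runif(n, 0, 4)
    int <- pmax(0L, as.integer(floor(real + 0.5)))
    expect_equal(silhouette_score(real, int), bf_silhouette(real, int))
  }
  expect_error(silhouette_score(1, 1L), "2 samples")
})

test_that("final filter enforces type, silhouette and length caps", {
  cnvrs <- data.frame(
    type = c("loss", "gain", "loss", "none", "both"),
    silhouette = c(0.9, 0.9, 0.9, 0.9, 0.6),
    length = c(60000, 400000, 40000, 1000, 10000),
    stringsAsFactors = FALSE)
  kept <- filter_cnvrs(cnvrs)
  # 60 kb loss removed, 400 kb gain kept, silhouette == 0.6 removed (strict)
  expect_equal(kept$length, c(400000, 40000))
})

test_that("the full builder recovers a clean planted deletion", {
  g <- manual_genome(30, window_size = 800, gc = 0.5)
  rows <- lapply(1:20, function(i) rep(2, 30))
  names(rows) <- sprintf("s%02d", 1:20)
  cn <- cn_matrix(g, rows)
  cn[1:6, 11:15] <- 1
  cs <- build_cnvrs(cn, g)
  expect_equal(nrow(cs$cnvrs), 1)
  expect_equal(cs$cnvrs$type, "loss")
  expect_equal(cs$cnvrs$loss_af, 0.3)
  expect_equal(cs$cnvrs$start, g$windows$start[11])
  expect_equal(cs$cnvrs$end, g$windows$end[15])
  expect_equal(cs$cnvrs$silhouette, 1.0)
  expect_equal(unname(cs$geno_int[1, 1:6]), rep(1L, 6))
  expect_equal(cs$cnvrs$id, rownames(cs$geno_real))
})
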