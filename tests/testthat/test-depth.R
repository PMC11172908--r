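test_that("uniform GC content makes the correction a no-op", {
  g <- manual_genome(50, gc = 0.5)
  d <- cn_matrix(g, list(s1 = rpois(50, 80) + 1))
  expect_equal(gc_correct(d, g), d, ignore_attr = TRUE)
})

test_that("two-bin median-ratio correction matches the hand computation", {
  # six windows, gc 0.3 (values 40/50/60) and 0.7 (90/100/110):
  # bin medians 50 and 100, global median (60+90)/2 = 75,
  # so bin-1 scales by 1.5 and bin-2 by 0.75
  g <- manual_genome(6, gc = c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7))
  d <- cn_matrix(g, list(s1 = c(40, 50, 60, 90, 100, 110)))
  corr <- gc_correct(d, g, n_bins = 2)
  expect_equal(unname(corr[1, ]), c(60, 75, 90, 67.5, 75, 82.5))
})

test_that("zero-median bins are flagged and left unchanged", {
  g <- manual_genome(6, gc = c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7))
  d <- cn_matrix(g, list(s1 = c(0, 0, 0, 90, 100, 110)))
  corr <- gc_correct(d, g, n_bins = 2)
  expect_equal(unname(corr[1, 1:3]), c(0, 0, 0))
  expect_true(length(attr(corr, "zero_bins")) > 0)
  expect_error(gc_correct(matrix(numeric(0), 0, 0), g), "empty")
})

test_that("injected quadratic GC bias is removed by binned correction", {
  g <- make_windowed_genome(c(chr1 = 1.2e6), gc_profile_seed = 9)
  tr <- plant_truth(g, c(A = 6),
                    data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), kind = character(0)),
                    seed = 1)
  d <- simulate_depth(g, tr, mean_coverage = 60, seed = 3)
  unm <- !g$windows$masked
  r_before <- apply(d[, unm], 1, function(x) cor(x, g$windows$gc[unm]))
  corr <- gc_correct(d, g)
  r_after <- apply(corr[, unm], 1, function(x) cor(x, g$windows$gc[unm]))
  expect_true(all(abs(r_after) < 0.1))
  expect_true(all(abs(r_after) < abs(r_before)))
})

test_that("normalization pins the per-sample median to the diploid state", {
  g <- manual_genome(5, gc = 0.5)
  d <- cn_matrix(g, list(s1 = c(10, 20, 30, 40, 50)))  # median 30
  cn <- normalize_copy_number(d, g)
  expect_equal(unname(cn[1, ]), 2 * c(10, 20, 30, 40, 50) / 30)
  expect_equal(unname(cn[1, 3]), 2.0)   # the median window
  # a window at twice the median is called CN 4
  d2 <- cn_matrix(g, list(s1 = c(30, 30, 30, 30, 60)))
  expect_equal(unname(normalize_copy_number(d2, g)[1, 5]), 4.0)
})

test_that("normalization errors name an all-zero sample and NA-masks windows", {
  g <- manual_genome(5, gc = 0.5, masked = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  d <- cn_matrix(g, list(good = c(10, 10, 99, 10, 10),
                         dead = c(0, 0, 0, 0, 0)))
  expect_error(normalize_copy_number(d, g), "dead")
  cn <- normalize_copy_number(d[1, , drop = FALSE], g)
  expect_true(is.na(cn[1, 3]))
  expect_equal(unname(cn[1, 1]), 2)
})

test_that("copy numbers are invariant to per-sample depth rescaling", {
  g <- make_windowed_genome(c(chr1 = 2e5), gc_profile_seed = 2)
  tr <- plant_truth(g, c(A = 3),
                    data.frame(chrom = "chr1", start = 40000, end = 48000,
                               kind = "gain", freq_A = 1,
                               stringsAsFactors = FALSE), seed = 1)
  d <- simulate_depth(g, tr, mean_coverage = 50, seed = 6)
  cn1 <- normalize_copy_number(gc_correct(d, g), g)
  d_scaled <- d
  d_scaled[2, ] <- d[2, ] * 3.7
  cn2 <- normalize_copy_number(gc_correct(d_scaled, g), g)
  expect_equal(cn1, cn2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("run-length segmentation reproduces hand-worked examples", {
  g <- manual_genome(7, gc = 0.5)
  flat <- cn_matrix(g, list(s1 = rep(2, 7)))
  expect_equal(nrow(call_sample_cnvs(flat, g)), 0)

  row <- cn_matrix(g, list(s1 = c(2, 2, 0.9, 1.0, 1.1, 2, 2)))
  calls <- call_sample_cnvs(row, g, loss_max = 1.5, gain_min = 2.5,
                            min_windows = 2, max_gap_windows = 0)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "loss")
  expect_equal(calls$start, g$windows$start[3])
  expect_equal(calls$end, g$windows$end[5])
  expect_equal(calls$mean_cn, 1.0)
  expect_equal(calls$n_windows, 3L)

  # two gain runs separated by one normal window merge when gap = 1
  row2 <- cn_matrix(g, list(s1 = c(3, 3, 2, 3, 3, 2, 2)))
  merged <- call_sample_cnvs(row2, g, max_gap_windows = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_windows, 5L)
  expect_equal(merged$mean_cn, mean(c(3, 3, 2, 3, 3)))
  split <- call_sample_cnvs(row2, g, max_gap_windows = 0)
  expect_equal(nrow(split), 2)

  expect_error(call_sample_cnvs(row, g, loss_max = 2.5, gain_min = 2.6),
               "loss_max")
})

test_that("calls never overlap, never cross chromosomes, respect thresholds", {
  g <- make_windowed_genome(c(chr1 = 6e4, chr2 = 6e4), gc_profile_seed = 3,
                            mask_fraction = 0)
  set.seed(42)
  for (rep in 1:20) {
    vals <- sample(c(0.5, 1, 2, 2.2, 3, 4), 150, replace = TRUE,
                   prob = c(.05, .1, .6, .1, .1, .05))
    cn <- cn_matrix(g, list(s1 = vals))
    calls <- call_sample_cnvs(cn, g, max_gap_windows = 1)
    if (nrow(calls) < 2) next
    expect_true(all(calls$end > calls$start))
    # sorted and non-overlapping within chromosome
    for (chrom in unique(calls$chrom)) {
      cc <- calls[calls$chrom == chrom, ]
      if (nrow(cc) > 1)
        expect_true(all(cc$start[-1] >= cc$end[-nrow(cc)]))
    }
    # boundaries on window edges; kind consistent with mean
    expect_true(all(calls$start %% g$window_size == 0))
    expect_true(all(calls$mean_cn[calls$kind == "loss"] < 2))
    expect_true(all(calls$mean_cn[calls$kind == "gain"] > 2))
  }
})

test_that("planted regions are recovered by their carriers' calls", {
  co <- simulate_study_cohort(seed = 1)
  cn <- normalize_copy_number(gc_correct(co$depth, co$genome), co$genome)
  calls <- call_sample_cnvs(cn, co$genome)
  truth <- co$truth$regions
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    if ((r$end - r$start) / co$genome$window_size < 3) return(NA)
    carr <- co$truth$carriers[co$truth$carriers$region_id == r$region_id, ]
    hits <- vapply(carr$sample, function(smp) {
      cc <- calls[calls$sample == smp & calls$chrom == r$chrom, ]
      if (!nrow(cc)) return(FALSE)
      inter <- pmax(0, pmin(cc$end, r$end) - pmax(cc$start, r$start))
      any(pmin(inter / (r$end - r$start), inter / (cc$end - cc$start)) >= 0.8)
    }, logical(1))
    mean(hits) >= 0.5   # the majority of carriers see the variant
  }, logical(1))
  expect_gte(mean(recovered, na.rm = TRUE), 0.95)
})

test_that("depth matrices round-trip through TSV", {
  m <- matrix(as.numeric(rpois(12, 40)), 3, 4,
              dimnames = list(c("a", "b", "c"),
                              sprintf("chr1:%d-%d", c(1, 101, 201, 301),
                                      c(100, 200, 300, 400))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(m, path)
  m2 <- read_depth_matrix(path)
  expect_equal(m2, m, ignore_attr = FALSE)
})
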