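test_that("equal-width binning tiles chromosomes exactly", {
  g <- genome_layout(c(chr1 = 1e7))
  b <- make_bins(g, 10)
  expect_equal(nrow(b), 10)
  expect_true(all(b$end - b$start == 1e6))
  expect_equal(b$start[1], 0)
  expect_equal(b$end[10], 1e7)
  expect_error(make_bins(g, 0), "one bin")
  expect_error(make_bins(genome_layout(c(chr1 = 5)), 10), "exceeds")
})

test_that("weighted binning equalizes mappable positions and skips deserts", {
  g <- genome_layout(c(chr1 = 1e7))
  wt <- tibble(chrom = "chr1",
               start = c(0, 4e6, 6e6), end = c(4e6, 6e6, 1e7),
               weight = c(1, 0, 1))   # 2 Mb desert in the middle
  b <- make_bins(g, 8, weights = wt)
  expect_equal(nrow(b), 8)
  # per-bin mappable weight is the quota within rounding slack
  bin_w <- purrr::map2_dbl(b$start, b$end, function(s, e) {
    sum(pmax(0, pmin(e, wt$end) - pmax(s, wt$start)) * wt$weight)
  })
  expect_true(all(abs(bin_w - 1e6) <= 1))
  # no bin boundary strictly inside the desert interior
  inner <- b$start[b$start > 4e6 & b$start < 6e6]
  expect_true(all(inner %in% c(4e6, 6e6)) || length(inner) <= 1)
})

test_that("bin allocation scales to a genome-wide scheme", {
  b <- make_bins(human_like_genome(3e9), 10000)
  expect_equal(nrow(b), 10000)
  expect_true(all(b$end > b$start))
  widths <- b$end - b$start
  expect_lt(max(widths) / min(widths), 1.2)
})

test_that("spike-in multiplies counts by the copy ratio R = N/2", {
  g <- genome_layout(c(chr1 = 1e6))
  bins <- make_bins(g, 10)
  counts <- mutate(bins, count = 100)
  r <- cnv_regions(tibble(chrom = "chr1", start = 0, end = 3e5,
                          copy_number = 4))
  out <- spike_in(counts, r)
  expect_equal(out$count[1:3], rep(200, 3))
  expect_equal(out$count[4:10], rep(100, 7))
  # R = 1 everywhere is the identity
  r1 <- cnv_regions(tibble(chrom = "chr1", start = 0, end = 1e6,
                           copy_number = 2))
  expect_equal(spike_in(counts, r1)$count, counts$count)
  # N = 0 zeroes fully covered bins
  r0 <- cnv_regions(tibble(chrom = "chr1", start = 0, end = 2e5,
                           copy_number = 0))
  expect_equal(spike_in(counts, r0)$count[1:2], c(0, 0))
  # partial overlap uses the length-weighted ratio
  rp <- cnv_regions(tibble(chrom = "chr1", start = 0, end = 1.5e5,
                           copy_number = 4))
  expect_equal(spike_in(counts, rp)$count[2], 150)
  expect_error(cnv_regions(tibble(chrom = "chr1", start = 0, end = 10,
                                  copy_number = -2)), "non-negative")
})

test_that("ratio normalization is scale invariant and GC-correctable", {
  g <- genome_layout(c(chr1 = 1e7))
  bins <- make_bins(g, 1000)
  counts <- mutate(bins, count = 500L)
  expect_equal(normalize_ratio(counts)$ratio, rep(1, 1000))
  noisy <- simulate_binned_counts(bins, seed = 3)
  doubled <- mutate(noisy, count = count * 2L)
  expect_equal(normalize_ratio(noisy)$ratio, normalize_ratio(doubled)$ratio,
               tolerance = 1e-9)
  expect_equal(mean(normalize_ratio(noisy)$ratio), 1, tolerance = 1e-6)
  # GC-coupled counts decorrelate after correction
  withr::with_seed(11, {
    gcs <- runif(1000, 0.3, 0.6)
    gc_counts <- mutate(bins, gc = gcs,
                        count = rpois(1000, 500 * (1 + 2 * gcs)))
  })
  raw <- normalize_ratio(gc_counts, gc_correct = FALSE)
  corrected <- normalize_ratio(gc_counts, gc_correct = TRUE)
  expect_gt(abs(cor(raw$ratio, raw$gc)), 0.5)
  expect_lt(abs(cor(corrected$ratio, corrected$gc)), 0.05)
  expect_error(normalize_ratio(mutate(bins, count = 0)), "positive")
})

test_that("noise-free piecewise-constant input is recovered exactly", {
  g <- genome_layout(c(chr1 = 2.5e7))
  bins <- make_bins(g, 250)
  ratios <- mutate(bins, ratio = rep(c(1, 2, 1), c(100, 50, 100)))
  segs <- segment_ratios(ratios, seed = 4)
  expect_equal(nrow(segs$segments), 3)
  expect_equal(segs$segments$n_bins, c(100, 50, 100))
  expect_equal(segs$segments$mean_ratio, c(1, 2, 1))
})

test_that("a focal amplification is located with an accurate mean", {
  g <- genome_layout(c(chr1 = 5e7))
  bins <- make_bins(g, 500)
  withr::with_seed(21, {
    r <- rnorm(500, 1, 0.1)
    r[241:260] <- rnorm(20, 2, 0.1)
  })
  segs <- segment_ratios(mutate(bins, ratio = r), seed = 5)
  amp <- filter(tidy(segs), .data$mean_ratio > 1.5)
  expect_equal(nrow(amp), 1)
  expect_lt(abs(amp$mean_ratio - 2), 0.1)
  expect_lt(abs(amp$start_bin - 241), 2)
  expect_lt(abs(amp$end_bin - 260), 2)
})

test_that("segmentation is deterministic and respects per-chromosome bounds", {
  g <- toy_genome(3, 1e7)
  bins <- make_bins(g, 300)
  ratios <- simulate_binned_counts(bins, seed = 6) |> normalize_ratio()
  a <- segment_ratios(ratios, seed = 7)
  b <- segment_ratios(ratios, seed = 7)
  expect_identical(tidy(a), tidy(b))
  # segments never span chromosomes
  expect_true(all(table(tidy(a)$chrom) >= 1))
  for (s in seq_len(nrow(tidy(a)))) {
    seg <- tidy(a)[s, ]
    expect_equal(unique(a$bins$chrom[seg$start_bin:seg$end_bin]), seg$chrom)
  }
  expect_error(segment_ratios(ratios[1, ]), "Fewer bins")
})

test_that("mode anchoring maps the dominant ratio to copy number two", {
  g <- genome_layout(c(chr1 = 1e7))
  bins <- make_bins(g, 100)
  ratios <- mutate(bins, ratio = rep(c(1, 2), c(80, 20)))
  segs <- mode_normalize(segment_ratios(ratios, seed = 8))
  expect_equal(segs$mode, 1, tolerance = 0.05)
  expect_equal(sort(unique(round(segs$segments$copy_number, 1))), c(2, 4),
               tolerance = 0.1)
  # invariance under global rescaling
  segs3 <- mode_normalize(segment_ratios(mutate(ratios, ratio = ratio * 3),
                                         seed = 8))
  expect_equal(segs3$segments$copy_number, segs$segments$copy_number,
               tolerance = 1e-6)
  # heavier mass below wins a bimodal density (tetraploid-like ambiguity)
  ratios2 <- mutate(bins, ratio = rep(c(0.5, 1), c(70, 30)))
  segs2 <- mode_normalize(segment_ratios(ratios2, seed = 9))
  expect_equal(segs2$mode, 0.5, tolerance = 0.05)
})

test_that("CNV calling applies thresholds, merging and the length filter", {
  g <- genome_layout(c(chr1 = 5e7))
  bins <- make_bins(g, 500)   # 100 kb bins
  flat <- mode_normalize(segment_ratios(mutate(bins, ratio = 1 +
    withr::with_seed(31, rnorm(500, 0, 0.01))), seed = 10))
  expect_equal(nrow(call_cnvs(flat)), 0)

  r <- rep(1, 500); r[101:150] <- 2   # 5 Mb at CN 4
  segs <- mode_normalize(segment_ratios(mutate(bins, ratio = r), seed = 11))
  calls <- call_cnvs(segs)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$end - calls$start, 5e6)

  r2 <- rep(1, 500); r2[101:108] <- 2  # 0.8 Mb aberration
  segs2 <- mode_normalize(segment_ratios(mutate(bins, ratio = r2), seed = 12))
  expect_equal(nrow(call_cnvs(segs2, min_length = 1e6)), 0)
  expect_equal(nrow(call_cnvs(segs2, min_length = 5e5)), 1)
})

test_that("overlap-length evaluation follows the L, LC, LT definitions", {
  calls <- tibble(chrom = "chr1", start = 1e6, end = 3e6,
                  copy_number = 4, direction = "gain")
  ctrl <- tibble(chrom = "chr1", start = 0, end = 2e6,
                 copy_number = 4, direction = "gain")
  ev <- evaluate_cnvs(calls, ctrl)
  expect_equal(ev$L_T, 1e6)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$specificity, 0.5)
  # identity and symmetry
  expect_equal(evaluate_cnvs(calls, calls)$sensitivity, 1)
  ev_swap <- evaluate_cnvs(ctrl, calls)
  expect_equal(ev_swap$sensitivity, ev$specificity)
  expect_equal(ev_swap$specificity, ev$sensitivity)
  expect_lte(ev$L_T, min(ev$L, ev$L_C))
  # direction-aware mode zeroes mismatched directions
  ctrl_loss <- mutate(ctrl, direction = "loss")
  expect_equal(evaluate_cnvs(calls, ctrl_loss, require_direction = TRUE)$L_T, 0)
  # undefined denominators are NA, not zero
  empty <- calls[0, ]
  expect_true(is.na(evaluate_cnvs(empty, ctrl)$specificity))
  expect_true(is.na(evaluate_cnvs(calls, empty)$sensitivity))
})
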