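test_that("golden-control simulation honours proportions and determinism", {
  g <- tiny_genome()
  all_ref <- simulate_golden_control(g, 1000, c(1, 0, 0), seed = 1)
  expect_true(all(all_ref$category == "HOMref"))
  expect_true(all(all_ref$a1 == all_ref$ref & all_ref$a2 == all_ref$ref))

  a <- simulate_golden_control(g, 500, seed = 42)
  b <- simulate_golden_control(g, 500, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_golden_control(g, 500, seed = 43)))

  by_chrom <- split(a$pos, a$chrom)
  for (p in by_chrom) expect_true(all(diff(p) > 0))

  expect_error(simulate_golden_control(g, 3e7, seed = 1), "exceeds")
  expect_error(simulate_golden_control(g, 10, c(0.5, 0.5, 0.5), seed = 1),
               "summing to 1")
})

test_that("golden-control category counts match the multinomial at scale", {
  # a 1 % scale model of the 2,206,364-site lymphoblastoid control
  n <- 22064
  gc <- simulate_golden_control(toy_genome(4, 5e7), n, yh_proportions,
                                seed = 7)
  obs <- table(factor(gc$category, c("HOMref", "HOMmut", "HETref")))
  exp_counts <- n * yh_proportions
  sds <- sqrt(n * yh_proportions * (1 - yh_proportions))
  expect_true(all(abs(as.numeric(obs) - exp_counts) <= 3 * sds))
})

test_that("single-cell call simulation reduces to the control without noise", {
  g <- tiny_genome()
  gc <- simulate_golden_control(g, 2000, seed = 3)
  calls <- simulate_single_cell_calls(gc, method_profile("clean"), seed = 5)
  expect_equal(nrow(calls), nrow(gc))
  expect_equal(calls$a1, gc$a1)
  expect_equal(calls$a2, gc$a2)
  expect_true(all(calls$truth == "faithful"))
})

test_that("ADO events hit heterozygous sites at the configured rate", {
  g <- tiny_genome()
  het_only <- simulate_golden_control(g, 10000, c(0, 0, 1), seed = 11)
  prof <- method_profile("ado", ado_rate = 0.334)
  calls <- simulate_single_cell_calls(het_only, prof, seed = 12)
  n_ado <- sum(calls$truth == "ADO")
  expect_lt(abs(n_ado - 10000 * 0.334), 3 * sqrt(10000 * 0.334 * 0.666))
  # every labelled ADO call is homozygous for an allele the control carried
  j <- inner_join(calls[calls$truth == "ADO", ], het_only,
                  by = c("chrom", "pos"), suffix = c(".sc", ".ctl"))
  expect_true(all(j$a1.sc == j$a2.sc))
  expect_true(all(j$a1.sc == j$a1.ctl | j$a1.sc == j$a2.ctl))
})

test_that("FP events occur at the configured per-site rate and are discordant", {
  g <- tiny_genome()
  gc <- simulate_golden_control(g, 50000, seed = 21)
  prof <- method_profile("fp", fp_rate = 1e-3)
  calls <- simulate_single_cell_calls(gc, prof, seed = 22)
  n_fp <- sum(calls$truth == "FP")
  expect_lt(abs(n_fp - 5e4 * 1e-3), 3 * sqrt(5e4 * 1e-3 * (1 - 1e-3)))
  j <- inner_join(calls[calls$truth == "FP", ], gc,
                  by = c("chrom", "pos"), suffix = c(".sc", ".ctl"))
  expect_true(all(allele_share(j$a1.sc, j$a2.sc, j$a1.ctl, j$a2.ctl) < 2))
})

test_that("site coverage thins the callable set binomially", {
  g <- tiny_genome()
  gc <- simulate_golden_control(g, 20000, seed = 31)
  prof <- method_profile("cov", site_coverage = 0.5187)
  calls <- simulate_single_cell_calls(gc, prof, seed = 32)
  expect_lt(abs(nrow(calls) - 20000 * 0.5187),
            3 * sqrt(20000 * 0.5187 * 0.4813))
})

test_that("binned counts are Poisson in the zero-dispersion limit", {
  bins <- make_bins(tiny_genome(), 5000)
  cc <- simulate_binned_counts(bins, NULL, method_profile("poisson"),
                               mean_count_per_bin = 50, seed = 41)
  id <- var(cc$count) / mean(cc$count)
  expect_lt(abs(id - 1), 0.06)
  expect_true(all(cc$cn_truth == 2))
})

test_that("bin dispersion increases count variance monotonically", {
  bins <- make_bins(tiny_genome(), 5000)
  lo <- simulate_binned_counts(bins, NULL,
                               method_profile("lo", bin_dispersion = 0.1),
                               mean_count_per_bin = 100, seed = 51)
  hi <- simulate_binned_counts(bins, NULL,
                               method_profile("hi", bin_dispersion = 0.8),
                               mean_count_per_bin = 100, seed = 51)
  expect_gt(var(hi$count), var(lo$count))
})

test_that("a copy-number-4 region doubles the local mean count", {
  g <- genome_layout(c(chr1 = 1e7))
  bins <- make_bins(g, 1000)             # 10 kb bins
  truth <- cnv_regions(tibble(chrom = "chr1", start = 2e6, end = 3e6,
                              copy_number = 4))   # covers 100 bins
  cc <- simulate_binned_counts(bins, truth, method_profile("amp"),
                               mean_count_per_bin = 200, seed = 61)
  inside <- cc$count[cc$start >= 2e6 & cc$end <= 3e6]
  outside <- cc$count[cc$end <= 2e6 | cc$start >= 3e6]
  ratio <- mean(inside) / mean(outside)
  se <- ratio * sqrt(var(inside) / (length(inside) * mean(inside)^2) +
                       var(outside) / (length(outside) * mean(outside)^2))
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("breakpoint simulation jitters truth and injects typed chimeras", {
  g <- tiny_genome()
  tb <- simulate_true_breakpoints(g, 50, seed = 71)
  quiet <- simulate_breakpoints(tb, method_profile("q"), g, seed = 72)
  expect_equal(nrow(quiet$cell), 50)
  expect_true(all(quiet$cell$truth == "true"))
  expect_true(all(abs(quiet$cell$pos_a - quiet$control$pos_a) <= 50))
  expect_true(all(abs(quiet$cell$pos_b - quiet$control$pos_b) <= 50))

  noisy <- simulate_breakpoints(tb, wga_profiles()$mda2, g, seed = 73)
  chim <- noisy$cell[noisy$cell$truth == "chimera", ]
  expect_gt(nrow(chim), 0)
  expect_true(all(chim$type %in% c("ITX", "CTX", "DEL", "INS", "INV")))
  ctx <- chim$type == "CTX"
  expect_true(all((chim$chrom_a != chim$chrom_b) == ctx))
})

test_that("simulators are reproducible under a fixed seed", {
  g <- tiny_genome()
  gc <- simulate_golden_control(g, 1000, seed = 9)
  expect_identical(simulate_single_cell_calls(gc, wga_profiles()$mda2, seed = 2),
                   simulate_single_cell_calls(gc, wga_profiles()$mda2, seed = 2))
  bins <- make_bins(g, 200)
  expect_identical(simulate_binned_counts(bins, seed = 4),
                   simulate_binned_counts(bins, seed = 4))
  tb <- simulate_true_breakpoints(g, 20, seed = 6)
  expect_identical(simulate_breakpoints(tb, wga_profiles()$mda2, g, seed = 8),
                   simulate_breakpoints(tb, wga_profiles()$mda2, g, seed = 8))
})
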