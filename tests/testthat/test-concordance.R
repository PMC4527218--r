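test_that("genotype categories follow the reference-based definitions", {
  expect_equal(classify_genotype("A", "A", "A"), "HOMref")
  expect_equal(classify_genotype("T", "T", "A"), "HOMmut")
  expect_equal(classify_genotype("A", "T", "A"), "HETref")
  expect_error(classify_genotype("C", "T", "A"), "permissive")
  expect_equal(classify_genotype("C", "T", "A", permissive = TRUE), "HETnonref")
  expect_error(classify_genotype("A", "N", "A"), "Alleles")
})

test_that("allele share is the multiset intersection size", {
  expect_equal(allele_share("A", "T", "A", "T"), 2L)
  expect_equal(allele_share("A", "A", "A", "T"), 1L)
  expect_equal(allele_share("A", "A", "T", "T"), 0L)
  # symmetry and self-share over all unordered pairs
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a1 = bases, a2 = bases, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    g <- pairs[i, ]
    expect_equal(allele_share(g$a1, g$a2, g$a1, g$a2), 2L)
    for (j in seq_len(nrow(pairs))) {
      h <- pairs[j, ]
      expect_equal(allele_share(g$a1, g$a2, h$a1, h$a2),
                   allele_share(h$a1, h$a2, g$a1, g$a2))
    }
  }
})

test_that("golden-control construction intersects bulks and chip sites", {
  bulk1 <- tibble(chrom = "chr1", pos = 1:4, ref = "A",
                  a1 = c("A", "A", "T", "A"), a2 = c("A", "T", "T", "A"))
  bulk2 <- tibble(chrom = "chr1", pos = 1:4, ref = "A",
                  a1 = c("A", "A", "T", "C"), a2 = c("A", "T", "T", "C"))
  chip <- tibble(chrom = "chr1", pos = c(1, 2, 3),
                 a1 = c("A", "A", "A"), a2 = c("A", "T", "A"))
  gc <- build_golden_control(bulk1, chip, bulk2 = bulk2)
  # pos 4 removed by bulk disagreement, and is off-chip anyway
  expect_equal(gc$pos, c(1, 2, 3))
  expect_equal(gc$category, c("HOMref", "HETref", "HOMmut"))
  # chip genotype match additionally removes pos 3 (chip says HOMref)
  gc2 <- build_golden_control(bulk1, chip, bulk2 = bulk2, require_match = TRUE)
  expect_equal(gc2$pos, c(1, 2))
  expect_error(build_golden_control(bulk1, tibble(chrom = "chr9", pos = 1)),
               "Empty golden control")
})

test_that("a perfect single cell gives diagonal share-2 mass and 100 % metrics", {
  gc <- simulate_golden_control(tiny_genome(), 2000, seed = 2)
  cm <- concordance_matrix(gc[, c("chrom", "pos", "a1", "a2")], gc)
  expect_true(all(cm$cells$share == 2))
  expect_true(all(as.character(cm$cells$sc_category) ==
                    as.character(cm$cells$control_category)))
  expect_equal(cgde(cm)$cgde, rep(1, 4))
  expect_equal(consistency(cm)$consistency, rep(1, 4))
})

test_that("an ADO-style call lands in the homozygous row at share level 1", {
  control <- tibble(chrom = "chr1", pos = 100, ref = "A",
                    a1 = "A", a2 = "T", category = "HETref")
  calls <- tibble(chrom = "chr1", pos = 100, a1 = "A", a2 = "A")
  cm <- concordance_matrix(calls, control)
  expect_equal(nrow(cm$cells), 1)
  expect_equal(as.character(cm$cells$sc_category), "HOMref")
  expect_equal(as.character(cm$cells$control_category), "HETref")
  expect_equal(cm$cells$share, 1L)
})

test_that("homozygous share-1 mass under the HETref column equals the ADO truth", {
  gc <- simulate_golden_control(tiny_genome(), 20000, seed = 5)
  prof <- method_profile("m", ado_rate = 0.334, fp_rate = 1e-3,
                         site_coverage = 0.9)
  calls <- simulate_single_cell_calls(gc, prof, seed = 6)
  cm <- concordance_matrix(calls, gc)
  ado_cells <- cm$cells |>
    filter(.data$control_category == "HETref", .data$share == 1,
           .data$sc_category %in% c("HOMref", "HOMmut"))
  expect_equal(sum(ado_cells$count), sum(calls$truth == "ADO"))
})

test_that("estimator event counts equal simulation truth labels exactly", {
  gc <- simulate_golden_control(tiny_genome(), 30000, seed = 8)
  prof <- method_profile("m", ado_rate = 0.05, fp_rate = 1e-3,
                         site_coverage = 0.8)
  calls <- simulate_single_cell_calls(gc, prof, seed = 9)
  est <- estimate_artifact_rates(calls, gc)
  expect_identical(est$ado_count, sum(calls$truth == "ADO"))
  expect_identical(est$fp_count, sum(calls$truth == "FP"))
  expect_identical(est$covered_sites, nrow(calls))
})

test_that("concordance objects rebuilt from counts reproduce their marginals", {
  cm <- fixture_concordance("mda_yh")
  cv <- cgde(cm)
  expect_equal(cv$detected[1:3], unname(cm$detected_totals))
  expect_true(all(cv$cgde <= 1))
  cs <- consistency(cm)
  expect_true(all(cs$consistency <= 1, na.rm = TRUE))
  # invariant: total cell mass equals total detected (self-consistent table)
  expect_equal(sum(cm$cells$count), sum(cm$detected_totals), tolerance = 1e-6)
  expect_error(concordance_from_counts(
    tibble(sc_category = "HOMref", control_category = "HOMref",
           share = 2, count = 10),
    control_totals = c(HOMref = 5, HOMmut = 5, HETref = 5)),
    "exceed")
})

test_that("snv metrics are exact for a cell identical to its bulk", {
  gc <- simulate_golden_control(tiny_genome(), 5000, seed = 12)
  sm <- snv_metrics(gc[, c("chrom", "pos", "ref", "a1", "a2")], gc)
  expect_equal(sm$ado_ratio, 0)
  expect_equal(sm$fp_ratio, 0)
  expect_equal(sm$efficiency_gross, 1)
  expect_equal(sm$efficiency_net, 1)
})

test_that("snv metrics count ADO and FP events against the bulk", {
  bulk <- tibble(chrom = "chr1", pos = 1:5, ref = "A",
                 a1 = c("A", "A", "T", "C", "A"),
                 a2 = c("T", "T", "T", "C", "A"))
  # site 1: faithful het; site 2: ADO (hom for bulk allele);
  # site 3: faithful hom; site 4: undetected; site 5 stays hom-ref;
  # site 6: FP (not in bulk SNV set)
  calls <- tibble(chrom = "chr1", pos = c(1, 2, 3, 5, 6),
                  ref = c("A", "A", "A", "A", "G"),
                  a1 = c("A", "T", "T", "A", "G"),
                  a2 = c("T", "T", "T", "A", "C"))
  sm <- snv_metrics(calls, bulk)
  expect_equal(sm$ado_count, 1)
  expect_equal(sm$detected_het, 2)   # pos 1 and the FP het at pos 6
  expect_equal(sm$fp_het, 1)
  expect_equal(sm$detected_hom, 2)   # pos 3, plus the hom-alt ADO call at pos 2
  expect_equal(sm$control_het, 2)
  expect_equal(sm$control_hom, 2)
  expect_equal(sm$ado_ratio, 1 / 3)
})

test_that("tidy and glance summarise concordance and snv objects", {
  cm <- fixture_concordance("mda_yh")
  expect_named(glance(cm), c("cgde_overall", "consistency_overall",
                             "detected_total", "control_total", "n_excluded"))
  expect_s3_class(tidy(cm), "tbl_df")
  sm <- snv_metrics_from_counts(10, 5, 1, 0, 2, 20, 10)
  expect_equal(glance(sm)$ado_ratio, 2 / 12)
  expect_equal(nrow(tidy(sm)), 3)
})
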