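#' Classify a genotype against the reference base
#'
#' Genotypes are unordered allele pairs. The three categories used by the
#' golden-control comparison are `HOMref` (both alleles equal the reference),
#' `HOMmut` (both alleles equal each other and differ from the reference) and
#' `HETref` (exactly one allele equals the reference). A heterozygote with
#' neither allele equal to the reference has no slot in this scheme; it is
#' rejected unless `permissive = TRUE`, in which case it is labelled
#' `HETnonref` and excluded from category tabulations downstream.
#'
#' @param a1,a2 Allele vectors (single bases in `A`, `C`, `G`, `T`).
#' @param ref Reference allele vector.
#' @param permissive Map heterozygous-nonref genotypes to `"HETnonref"`
#'   instead of erroring.
#' @return Character vector of categories.
#' @examples
#' classify_genotype(c("A", "T", "A"), c("A", "T", "T"), ref = c("A", "A", "A"))
#' @export
classify_genotype <- function(a1, a2, ref, permissive = FALSE) {
  bases <- c("A", "C", "G", "T")
  if (!all(c(a1, a2, ref) %in% bases)) abort("Alleles must be A, C, G or T.")
  out <- ifelse(a1 == a2,
                ifelse(a1 == ref, "HOMref", "HOMmut"),
                ifelse(a1 == ref | a2 == ref, "HETref", "HETnonref"))
  if (!permissive && any(out == "HETnonref")) {
    abort("Heterozygous genotype with neither allele equal to the reference; use `permissive = TRUE` to label these HETnonref.")
  }
  out
}

#' Count alleles shared between two genotypes
#'
#' The share level is the size of the multiset intersection of the two
#' allele pairs: 2 when the genotypes agree at both alleles, 1 at one
#' allele, 0 when inconsistent at both. It is symmetric and
#' `allele_share(g, g) == 2` for every genotype.
#'
#' @param a1,a2 Alleles of the first genotype.
#' @param b1,b2 Alleles of the second genotype.
#' @return Integer vector in `{0, 1, 2}`.
#' @examples
#' allele_share("A", "A", "A", "T")  # 1
#' @export
allele_share <- function(a1, a2, b1, b2) {
  share <- integer(length(a1))
  for (b in c("A", "C", "G", "T")) {
    share <- share + pmin((a1 == b) + (a2 == b), (b1 == b) + (b2 == b))
  }
  as.integer(share)
}

genotype_key <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))

#' Build a golden-control genotype set
#'
#' The golden control is the consensus genotype baseline against which
#' single-cell calls are judged. With two bulk replicates, only sites
#' genotyped identically in both survive (removing residual sequencing
#' error); the survivors are then restricted to the positions assayed on a
#' SNP array. With one bulk, its callable genotypes are restricted to array
#' positions directly. Categories are assigned with [classify_genotype()];
#' heterozygous-nonref genotypes are excluded (their count is recorded in
#' the `n_excluded` attribute).
#'
#' @param bulk A genotype tibble: `chrom`, `pos` (1-based), `ref`, `a1`,
#'   `a2`, optional logical `callable`.
#' @param chip Array site tibble: `chrom`, `pos`, optional `a1`, `a2`.
#' @param bulk2 Optional second bulk replicate (same columns as `bulk`).
#' @param require_match Also require the bulk genotype to equal the array
#'   genotype (needs `a1`, `a2` on `chip`); default is positional
#'   restriction only.
#' @return A golden-control tibble (`chrom`, `pos`, `ref`, `a1`, `a2`,
#'   `category`).
#' @export
build_golden_control <- function(bulk, chip, bulk2 = NULL,
                                 require_match = FALSE) {
  prep <- function(x) {
    x <- as_tibble(x)
    if ("callable" %in% names(x)) x <- filter(x, .data$callable)
    srt <- sort_alleles(x$a1, x$a2)
    x$a1 <- srt$a1; x$a2 <- srt$a2
    x
  }
  b1 <- prep(bulk)
  if (!is.null(bulk2)) {
    b2 <- prep(bulk2)
    b1 <- inner_join(b1, b2, by = c("chrom", "pos"),
                     suffix = c("", ".rep")) |>
      filter(.data$a1 == .data$a1.rep, .data$a2 == .data$a2.rep,
             .data$ref == .data$ref.rep) |>
      select(all_of(c("chrom", "pos", "ref", "a1", "a2")))
  }
  chip <- as_tibble(chip)
  keep <- semi_join(b1, chip, by = c("chrom", "pos"))
  if (require_match) {
    if (!"a1" %in% names(chip)) abort("`require_match = TRUE` needs chip genotypes.")
    srt <- sort_alleles(chip$a1, chip$a2)
    chip$a1 <- srt$a1; chip$a2 <- srt$a2
    keep <- inner_join(keep, chip, by = c("chrom", "pos"),
                       suffix = c("", ".chip")) |>
      filter(.data$a1 == .data$a1.chip, .data$a2 == .data$a2.chip) |>
      select(all_of(c("chrom", "pos", "ref", "a1", "a2")))
  }
  if (nrow(keep) == 0) abort("Empty golden control: no sites survive the intersection.")
  cat3 <- classify_genotype(keep$a1, keep$a2, keep$ref, permissive = TRUE)
  n_excluded <- sum(cat3 == "HETnonref")
  out <- keep[cat3 != "HETnonref", ]
  out$category <- cat3[cat3 != "HETnonref"]
  attr(out, "n_excluded") <- n_excluded
  out
}

cat_levels <- c("HOMref", "HOMmut", "HETref")

#' Cross-tabulate single-cell genotypes against a golden control
#'
#' Iterates over golden-control sites only. Every control site genotyped in
#' the single cell contributes one count to the cell
#' `(single-cell category, control category, share level)`, where the share
#' level is the number of alleles the two genotypes have in common
#' ([allele_share()]). Control sites without a single-cell call count as
#' undetected. Single-cell calls at positions outside the control are
#' ignored here (they are false-positive candidates for [snv_metrics()]);
#' heterozygous-nonref single-cell calls are excluded from the three-category
#' table and reported in `n_excluded`.
#'
#' @param calls Single-cell calls tibble: `chrom`, `pos`, `a1`, `a2`,
#'   optional logical `callable`.
#' @param control Golden-control tibble (see [build_golden_control()] or
#'   [simulate_golden_control()]).
#' @return A `wga_concordance` object; see [cgde()], [consistency()],
#'   [tidy()], [glance()].
#' @export
concordance_matrix <- function(calls, control) {
  calls <- as_tibble(calls)
  if ("callable" %in% names(calls)) calls <- filter(calls, .data$callable)
  srt <- sort_alleles(calls$a1, calls$a2)
  calls$a1 <- srt$a1; calls$a2 <- srt$a2

  joined <- inner_join(control, calls, by = c("chrom", "pos"),
                       suffix = c(".ctl", ".sc"))
  sc_cat <- classify_genotype(joined$a1.sc, joined$a2.sc, joined$ref,
                              permissive = TRUE)
  share <- allele_share(joined$a1.sc, joined$a2.sc,
                        joined$a1.ctl, joined$a2.ctl)
  keep <- sc_cat != "HETnonref"
  cells <- tibble(sc_category = factor(sc_cat[keep], cat_levels),
                  control_category = factor(joined$category[keep], cat_levels),
                  share = share[keep]) |>
    count(.data$sc_category, .data$control_category, .data$share,
          name = "count") |>
    mutate(count = as.numeric(.data$count))

  control_totals <- table(factor(control$category, cat_levels))
  detected <- tapply(rep(1, sum(keep)),
                     factor(joined$category[keep], cat_levels), sum)
  detected[is.na(detected)] <- 0
  new_wga_concordance(cells,
                      control_totals = as.numeric(control_totals),
                      detected_totals = as.numeric(detected),
                      n_excluded = sum(!keep))
}

new_wga_concordance <- function(cells, control_totals, detected_totals,
                                n_excluded = 0) {
  structure(list(cells = cells,
                 control_totals = setNames(control_totals, cat_levels),
                 detected_totals = setNames(detected_totals, cat_levels),
                 n_excluded = n_excluded),
            class = "wga_concordance")
}

#' Assemble a concordance object from pre-tabulated counts
#'
#' Builds the same object [concordance_matrix()] produces, but from a table
#' of `(single-cell category, control category, share level, count)` cells —
#' the form in which published summaries are reported. When only the
#' marginal detected totals are available at higher precision than the cell
#' entries (e.g. averaged replicate tables), they can be supplied explicitly
#' and take precedence over the cell column sums.
#'
#' @param cells Tibble with columns `sc_category`, `control_category`,
#'   `share`, `count`.
#' @param control_totals Named (or HOMref/HOMmut/HETref-ordered) control site
#'   counts per category.
#' @param detected_totals Optional detected-per-control-category counts;
#'   defaults to the column sums of `cells`.
#' @return A `wga_concordance` object.
#' @export
concordance_from_counts <- function(cells, control_totals,
                                    detected_totals = NULL) {
  cells <- as_tibble(cells) |>
    mutate(sc_category = factor(.data$sc_category, cat_levels),
           control_category = factor(.data$control_category, cat_levels),
           count = as.numeric(.data$count))
  if (any(is.na(cells$sc_category)) || any(is.na(cells$control_category))) {
    abort("Categories must be HOMref, HOMmut or HETref.")
  }
  if (is.null(detected_totals)) {
    detected_totals <- cells |>
      group_by(.data$control_category) |>
      summarise(n = sum(.data$count), .groups = "drop")
    detected_totals <- setNames(detected_totals$n,
                                as.character(detected_totals$control_category))
  }
  ct <- unname(control_totals[cat_levels] %||% control_totals)
  dt <- if (!is.null(names(detected_totals))) {
    out <- setNames(rep(0, 3), cat_levels)
    out[names(detected_totals)] <- detected_totals
    unname(out)
  } else unname(detected_totals)
  if (any(dt > ct + 1e-6)) abort("Detected counts exceed control totals.")
  new_wga_concordance(cells, control_totals = ct, detected_totals = dt)
}

#' Consensus genotype detection efficiency (CGDE)
#'
#' The per-category CGDE (also reported as "coverage") is the fraction of
#' golden-control sites of that category genotyped in the single cell; the
#' overall value pools all categories.
#'
#' @param x A `wga_concordance` object.
#' @return A tibble with columns `category` (three categories plus
#'   `"overall"`), `detected`, `control`, `cgde`.
#' @export
cgde <- function(x) {
  stopifnot(inherits(x, "wga_concordance"))
  if (any(x$control_totals <= 0)) abort("Zero control-category total.")
  tibble(category = c(cat_levels, "overall"),
         detected = unname(c(x$detected_totals, sum(x$detected_totals))),
         control = unname(c(x$control_totals, sum(x$control_totals)))) |>
    mutate(cgde = .data$detected / .data$control)
}

#' Concordant ratio (consistency)
#'
#' Per single-cell category: the fraction of detected genotypes of that
#' category whose both alleles match the golden control (share level 2).
#' Overall: total share-2 count over total detected.
#'
#' @param x A `wga_concordance` object.
#' @return A tibble with columns `category`, `share2`, `detected`,
#'   `consistency`.
#' @export
consistency <- function(x) {
  stopifnot(inherits(x, "wga_concordance"))
  rows <- x$cells |>
    group_by(category = as.character(.data$sc_category)) |>
    summarise(share2 = sum(.data$count[.data$share == 2]),
              detected = sum(.data$count), .groups = "drop")
  rows <- left_join(tibble(category = cat_levels), rows, by = "category") |>
    mutate(across(c("share2", "detected"), ~ ifelse(is.na(.x), 0, .x)))
  total_detected <- sum(x$detected_totals)
  if (total_detected <= 0) abort("No detected sites.")
  overall <- tibble(category = "overall",
                    share2 = sum(rows$share2),
                    detected = total_detected)
  bind_rows(rows, overall) |>
    mutate(consistency = ifelse(.data$detected > 0,
                                .data$share2 / .data$detected, NA_real_))
}

#' @export
print.wga_concordance <- function(x, ...) {
  cat("<wga_concordance>\n")
  wide <- tidyr::pivot_wider(x$cells,
                             names_from = "control_category",
                             values_from = "count", values_fill = 0)
  print(as.data.frame(wide))
  cv <- cgde(x); cs <- consistency(x)
  cat(sprintf("overall CGDE %.2f %% | overall consistency %.2f %%",
              100 * cv$cgde[cv$category == "overall"],
              100 * cs$consistency[cs$category == "overall"]), "\n")
  if (x$n_excluded > 0) {
    cat(sprintf("(%d heterozygous-nonref call(s) excluded)\n", x$n_excluded))
  }
  invisible(x)
}

#' @export
tidy.wga_concordance <- function(x, ...) x$cells

#' @export
glance.wga_concordance <- function(x, ...) {
  cv <- cgde(x); cs <- consistency(x)
  tibble(cgde_overall = cv$cgde[cv$category == "overall"],
         consistency_overall = cs$consistency[cs$category == "overall"],
         detected_total = sum(x$detected_totals),
         control_total = sum(x$control_totals),
         n_excluded = x$n_excluded)
}

#' SNV detection efficiency, ADO ratio and FP ratio
#'
#' Compares a single cell's genotype calls with a bulk control at the SNV
#' level. An SNV is a call with at least one non-reference allele. Counts:
#' `detected_het` / `detected_hom` are the single cell's heterozygous /
#' homozygous SNV calls; `fp_*` are those at positions with no bulk SNV
#' (WGA-introduced alleles); `ado_count` is the number of bulk heterozygous
#' SNV sites where the single cell retains only one of the two alleles (the
#' call is homozygous for either bulk allele). Ratios:
#' `ado_ratio = ado / (detected_het + ado)`,
#' `fp_ratio = fp_total / genome_sites` (the number of assessable genomic
#' positions, default 3e9), gross efficiency `detected_total /
#' control_total` and net efficiency `(detected_total - fp_total) /
#' control_total`.
#'
#' @param calls Single-cell genotype tibble (`chrom`, `pos`, `a1`, `a2`,
#'   optional `ref`). If `ref` is absent it is taken from the bulk at shared
#'   positions, in which case every call position must occur in `bulk`.
#' @param bulk Bulk genotype tibble (`chrom`, `pos`, `ref`, `a1`, `a2`).
#' @param genome_sites Denominator for the FP ratio (default `3e9`).
#' @return A `wga_snv_metrics` object; see [tidy()] / [glance()].
#' @export
snv_metrics <- function(calls, bulk, genome_sites = 3e9) {
  calls <- as_tibble(calls); bulk <- as_tibble(bulk)
  srt <- sort_alleles(calls$a1, calls$a2); calls$a1 <- srt$a1; calls$a2 <- srt$a2
  srt <- sort_alleles(bulk$a1, bulk$a2);  bulk$a1 <- srt$a1;  bulk$a2 <- srt$a2
  if (!"ref" %in% names(calls)) {
    calls <- inner_join(calls, select(bulk, all_of(c("chrom", "pos", "ref"))),
                        by = c("chrom", "pos"))
  }
  bulk_snv <- filter(bulk, .data$a1 != .data$ref | .data$a2 != .data$ref) |>
    mutate(zygosity = ifelse(.data$a1 == .data$a2, "hom", "het"))
  control_het <- sum(bulk_snv$zygosity == "het")
  control_hom <- sum(bulk_snv$zygosity == "hom")
  if (nrow(bulk_snv) == 0) abort("Bulk control contains no SNVs.")

  cell_snv <- filter(calls, .data$a1 != .data$ref | .data$a2 != .data$ref) |>
    mutate(zygosity = ifelse(.data$a1 == .data$a2, "hom", "het"))
  in_bulk <- !is.na(
    left_join(cell_snv, mutate(bulk_snv, .hit = TRUE),
              by = c("chrom", "pos"), suffix = c("", ".b"))$.hit)

  detected_het <- sum(cell_snv$zygosity == "het")
  detected_hom <- sum(cell_snv$zygosity == "hom")
  fp_het <- sum(cell_snv$zygosity == "het" & !in_bulk)
  fp_hom <- sum(cell_snv$zygosity == "hom" & !in_bulk)

  het_sites <- inner_join(filter(bulk_snv, .data$zygosity == "het"),
                          calls, by = c("chrom", "pos"),
                          suffix = c(".b", ".sc"))
  ado_count <- sum(het_sites$a1.sc == het_sites$a2.sc &
                     (het_sites$a1.sc == het_sites$a1.b |
                        het_sites$a1.sc == het_sites$a2.b))

  snv_metrics_from_counts(detected_het = detected_het,
                          detected_hom = detected_hom,
                          fp_het = fp_het, fp_hom = fp_hom,
                          ado_count = ado_count,
                          control_het = control_het,
                          control_hom = control_hom,
                          genome_sites = genome_sites)
}

#' @param detected_het,detected_hom,fp_het,fp_hom,ado_count,control_het,control_hom
#'   Pre-tabulated counts (e.g. from a published summary table).
#' @param detected_total,fp_total,control_total Optional totals; default to
#'   the het + hom sums.
#' @rdname snv_metrics
#' @export
snv_metrics_from_counts <- function(detected_het, detected_hom,
                                    fp_het, fp_hom, ado_count,
                                    control_het, control_hom,
                                    detected_total = detected_het + detected_hom,
                                    fp_total = fp_het + fp_hom,
                                    control_total = control_het + control_hom,
                                    genome_sites = 3e9) {
  if (control_total <= 0) abort("Bulk control total must be positive.")
  if (fp_het > detected_het || fp_hom > detected_hom) {
    abort("FP counts cannot exceed detected counts.")
  }
  denom_ado <- detected_het + ado_count
  structure(list(
    detected_het = detected_het, detected_hom = detected_hom,
    detected_total = detected_total,
    fp_het = fp_het, fp_hom = fp_hom, fp_total = fp_total,
    ado_count = ado_count,
    control_het = control_het, control_hom = control_hom,
    control_total = control_total,
    genome_sites = genome_sites,
    ado_ratio = if (denom_ado > 0) ado_count / denom_ado else 0,
    fp_ratio = fp_total / genome_sites,
    efficiency_gross = detected_total / control_total,
    efficiency_net = (detected_total - fp_total) / control_total
  ), class = "wga_snv_metrics")
}

#' @export
print.wga_snv_metrics <- function(x, ...) {
  cat("<wga_snv_metrics>\n")
  cat(sprintf("  detected %s SNVs (het %s, hom %s) of %s in bulk\n",
              format(x$detected_total, big.mark = ","),
              format(x$detected_het, big.mark = ","),
              format(x$detected_hom, big.mark = ","),
              format(x$control_total, big.mark = ",")))
  cat(sprintf("  efficiency %.2f %% gross / %.2f %% net | ADO ratio %.4f | FP ratio %.3g\n",
              100 * x$efficiency_gross, 100 * x$efficiency_net,
              x$ado_ratio, x$fp_ratio))
  invisible(x)
}

#' @export
tidy.wga_snv_metrics <- function(x, ...) {
  tibble(zygosity = c("het", "hom", "total"),
         detected = c(x$detected_het, x$detected_hom, x$detected_total),
         fp = c(x$fp_het, x$fp_hom, x$fp_total),
         control = c(x$control_het, x$control_hom, x$control_total))
}

#' @export
glance.wga_snv_metrics <- function(x, ...) {
  tibble(efficiency_gross = x$efficiency_gross,
         efficiency_net = x$efficiency_net,
         ado_ratio = x$ado_ratio,
         fp_ratio = x$fp_ratio,
         ado_count = x$ado_count,
         fp_total = x$fp_total)
}

#' Estimate ADO and FP event rates against the generating control
#'
#' The direct per-site estimator used by the parameter-recovery suites:
#' among covered control heterozygous sites, the fraction called homozygous
#' for one of the control alleles estimates the ADO rate; among all covered
#' control sites, the fraction whose call is discordant with the control in
#' a non-ADO pattern estimates the FP rate. With the same control the
#' generator used, these counts equal the simulation truth labels exactly.
#'
#' @param calls Single-cell calls tibble (`chrom`, `pos`, `a1`, `a2`).
#' @param control Golden-control tibble.
#' @return A one-row tibble: `covered_sites`, `covered_het`, `ado_count`,
#'   `ado_rate`, `fp_count`, `fp_rate`, `site_coverage`.
#' @export
estimate_artifact_rates <- function(calls, control) {
  calls <- as_tibble(calls)
  srt <- sort_alleles(calls$a1, calls$a2); calls$a1 <- srt$a1; calls$a2 <- srt$a2
  j <- inner_join(control, calls, by = c("chrom", "pos"),
                  suffix = c(".ctl", ".sc"))
  share <- allele_share(j$a1.sc, j$a2.sc, j$a1.ctl, j$a2.ctl)
  is_het <- j$category == "HETref"
  is_hom_call <- j$a1.sc == j$a2.sc
  ado <- is_het & is_hom_call & share >= 1
  concordant <- share == 2
  fp <- !concordant & !ado
  tibble(covered_sites = nrow(j),
         covered_het = sum(is_het),
         ado_count = sum(ado),
         ado_rate = ifelse(sum(is_het) > 0, sum(ado) / sum(is_het), NA_real_),
         fp_count = sum(fp),
         fp_rate = sum(fp) / nrow(j),
         site_coverage = nrow(j) / nrow(control))
}
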