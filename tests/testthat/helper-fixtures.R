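suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

tiny_genome <- function() toy_genome(n_chrom = 2, chrom_length = 1e7)

load_fixture <- function(name) {
  readr::read_tsv(system.file("extdata", name, package = "scwgaeval"),
                  show_col_types = FALSE, progress = FALSE)
}

# Golden-control category proportions of the YH-style control
# (HOMref : HOMmut : HETref = 1,584,649 : 270,225 : 351,490)
yh_proportions <- c(HOMref = 1584649, HOMmut = 270225, HETref = 351490) / 2206364

# Concordance objects rebuilt from the published per-category counts.
# The marginal detected totals are supplied explicitly: they are printed at
# higher precision than the averaged cell entries (see inst/extdata/README).
fixture_concordance <- function(stem) {
  cells <- load_fixture(paste0("concordance_", stem, "_cells.tsv"))
  totals <- load_fixture(paste0("concordance_", stem, "_totals.tsv"))
  concordance_from_counts(
    cells,
    control_totals = setNames(totals$control, totals$category),
    detected_totals = setNames(totals$detected, totals$category))
}

# Independent brute-force Mann-Whitney oracle: enumerate every assignment of
# the pooled observations to the two groups and compute the exact tail
# probability of the U statistic.
brute_force_mw_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  idx <- utils::combn(n, length(x))
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  switch(alternative,
         less = mean(us <= obs),
         greater = mean(us >= obs),
         two.sided = min(1, 2 * min(mean(us <= obs), mean(us >= obs))))
}
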