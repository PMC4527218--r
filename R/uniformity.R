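#' Normalized per-window read depth
#'
#' Each window's mean depth is divided by the genome-wide mean depth, where
#' the genome-wide mean is the width-weighted mean over the included
#' windows. The width-weighted mean of the output is therefore exactly 1,
#' and the result is invariant under any positive global rescaling of
#' depth. Windows narrower than `min_width_frac` of the modal window width
#' (chromosome-end remainders) are dropped to avoid edge effects.
#'
#' @param track Depth-track tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `depth`, optional `gc`.
#' @param autosomes Optional character vector of chromosomes to keep (e.g.
#'   autosome labels); default uses all supplied windows.
#' @param min_width_frac Drop windows narrower than this fraction of the
#'   modal window width (default 0.5).
#' @return The filtered track with an added `norm_depth` column.
#' @examples
#' tr <- tibble::tibble(chrom = "chr1", start = c(0, 1e5),
#'                      end = c(1e5, 2e5), depth = c(10, 30))
#' normalized_depth(tr)$norm_depth  # 0.5, 1.5
#' @export
normalized_depth <- function(track, autosomes = NULL, min_width_frac = 0.5) {
  track <- as_tibble(track)
  if (!is.null(autosomes)) track <- filter(track, .data$chrom %in% autosomes)
  w <- track$end - track$start
  modal_w <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  track <- track[w >= min_width_frac * modal_w, ]
  w <- track$end - track$start
  gm <- sum(track$depth * w) / sum(w)
  if (!is.finite(gm) || gm <= 0) abort("Genome-wide mean depth must be > 0.")
  track$norm_depth <- track$depth / gm
  track
}

#' Poisson reference for normalized depth
#'
#' Draws `n_draws` i.i.d. Poisson(`lambda`) depths and normalizes them by
#' `lambda`, giving the no-bias reference distribution a perfectly uniform
#' library would produce at that mean depth (default `lambda = 30`,
#' 1000 draws).
#'
#' @param lambda Poisson mean depth (> 0).
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `draw` (raw Poisson) and `norm` (`draw /
#'   lambda`).
#' @export
poisson_reference <- function(lambda = 30, n_draws = 1000, seed = 1L) {
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  withr::with_seed(seed, {
    d <- rpois(n_draws, lambda)
    tibble(draw = d, norm = d / lambda)
  })
}

#' Cumulative depth distribution
#'
#' Fraction of positions (or windows) with depth at least `t`, for each
#' threshold `t`. Non-increasing in `t`; equal to 1 at `t = 0`.
#'
#' @param depths Non-negative depth vector.
#' @param thresholds Non-negative thresholds.
#' @return A tibble with columns `threshold` and `fraction`.
#' @export
cumulative_depth_distribution <- function(depths, thresholds = 0:50) {
  if (length(depths) == 0) abort("Empty depth vector.")
  if (any(thresholds < 0)) abort("Thresholds must be non-negative.")
  tibble(threshold = thresholds,
         fraction = purrr::map_dbl(thresholds, ~ mean(depths >= .x)))
}

#' Stratify windows by GC content
#'
#' Windows with GC fraction strictly above `high` are `HighGC`, strictly
#' below `low` are `LowGC`, all others (including exact boundary values)
#' `MiddleGC`. Defaults: high 0.50, low 0.35.
#'
#' @param track Depth-track tibble with a `gc` column.
#' @param high,low GC cutoffs (fractions; `low < high`).
#' @return The track with an added `gc_stratum` column.
#' @export
gc_stratify <- function(track, high = 0.50, low = 0.35) {
  if (low >= high) abort("`low` cutoff must be below `high`.")
  if (!"gc" %in% names(track) || anyNA(track$gc)) abort("Windows must carry GC content.")
  track <- as_tibble(track)
  track$gc_stratum <- ifelse(track$gc > high, "HighGC",
                             ifelse(track$gc < low, "LowGC", "MiddleGC"))
  track
}

#' Normalized depth over regions
#'
#' For each region (e.g. Alu or L1 repeats) the mean depth of the windows or
#' positions it overlaps, divided by the genome-wide mean depth; overlaps
#' are length-weighted when a region partially covers a window.
#'
#' @param track Depth-track tibble (`chrom`, `start`, `end`, `depth`).
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based
#'   half-open); every region must have positive length.
#' @return The regions tibble with an added `norm_depth` column (`NA` for
#'   regions with no overlapping windows).
#' @export
region_normalized_depth <- function(track, regions) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) abort("Empty region set.")
  if (any(regions$end <= regions$start)) abort("Zero- or negative-length region.")
  w <- track$end - track$start
  gm <- sum(track$depth * w) / sum(w)
  if (!is.finite(gm) || gm <= 0) abort("Genome-wide mean depth must be > 0.")
  gt <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1, track$end))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(gr, gt)
  ov <- IRanges::width(IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                           gt[S4Vectors::subjectHits(hits)]))
  agg <- tibble(region = S4Vectors::queryHits(hits),
                depth = track$depth[S4Vectors::subjectHits(hits)],
                w = ov) |>
    group_by(.data$region) |>
    summarise(mean_depth = sum(.data$depth * .data$w) / sum(.data$w),
              .groups = "drop")
  regions$norm_depth <- NA_real_
  regions$norm_depth[agg$region] <- agg$mean_depth / gm
  regions
}

#' Mapping and duplication summary
#'
#' Mapping ratio is mapped / total reads; duplication ratio is duplicates /
#' mapped reads (duplicates are only defined among mapped reads).
#'
#' @param reads Tibble with logical columns `mapped` and `duplicate`.
#' @return A one-row tibble: `n_reads`, `n_mapped`, `n_duplicate`,
#'   `mapping_ratio`, `duplication_ratio`.
#' @export
mapping_summary <- function(reads) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) abort("No reads.")
  n <- nrow(reads)
  n_map <- sum(reads$mapped)
  if (n_map == 0) abort("Duplication ratio undefined: zero mapped reads.")
  n_dup <- sum(reads$duplicate & reads$mapped)
  tibble(n_reads = n, n_mapped = n_map, n_duplicate = n_dup,
         mapping_ratio = n_map / n,
         duplication_ratio = n_dup / n_map)
}

#' Pairwise reproducibility correlations
#'
#' Pearson correlation matrix between per-window normalized-depth or
#' copy-ratio vectors of several cells; the standard reproducibility
#' summary for single-cell libraries.
#'
#' @param vectors A numeric matrix (windows x cells), or a named list /
#'   data frame of at least two equal-length numeric vectors of length
#'   three or more.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pairwise_reproducibility <- function(vectors) {
  m <- if (is.matrix(vectors)) vectors else {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1) abort("Vectors must have equal length.")
    do.call(cbind, as.list(vectors))
  }
  if (ncol(m) < 2 || nrow(m) < 3) abort("Need >= 2 vectors of length >= 3.")
  if (any(apply(m, 2, sd) == 0)) abort("Zero-variance vector.")
  r <- cor(m)
  diag(r) <- 1
  r
}
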