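#' Partition a genome into bins
#'
#' Builds the bin scheme the copy-number pipeline counts reads in (default
#' 10,000 bins genome-wide). Without weights, bins within a chromosome have
#' equal width. With a mappability weight track, bin boundaries are placed
#' at equal-weight quantiles so every bin holds (approximately) the same
#' number of mappable positions; unmappable deserts then get absorbed into
#' their flanking bins. Bin boundaries never cross chromosomes; bins are
#' allocated to chromosomes proportionally to their total weight (length
#' when unweighted), at least one per chromosome.
#'
#' @param genome Genome layout tibble.
#' @param n_bins Total number of bins (>= number of chromosomes).
#' @param weights Optional mappability track: tibble `chrom`, `start`,
#'   `end` (0-based half-open), `weight` (non-negative density per bp).
#'   Positions not covered by the track have weight 0.
#' @return A bin tibble: `chrom`, `start`, `end` (0-based half-open).
#' @export
make_bins <- function(genome, n_bins = 10000, weights = NULL) {
  stopifnot(is.data.frame(genome))
  if (n_bins < nrow(genome)) abort("Need at least one bin per chromosome.")
  if (n_bins > sum(genome$length)) abort("`n_bins` exceeds available positions.")

  chrom_w <- if (is.null(weights)) genome$length else {
    purrr::map_dbl(genome$chrom, function(ch) {
      wt <- weights[weights$chrom == ch, ]
      sum((wt$end - wt$start) * wt$weight)
    })
  }
  if (any(chrom_w <= 0)) abort("Every chromosome needs positive total weight.")
  # largest-remainder apportionment, minimum one bin per chromosome
  raw <- n_bins * chrom_w / sum(chrom_w)
  alloc <- pmax(1L, floor(raw))
  rem <- n_bins - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    shrink <- order(alloc, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      if (alloc[shrink[i]] > 1L) { alloc[shrink[i]] <- alloc[shrink[i]] - 1L; rem <- rem + 1 }
      i <- if (i == length(shrink)) 1 else i + 1
    }
  }

  purrr::pmap_dfr(list(genome$chrom, genome$length, alloc),
                  function(ch, len, k) {
    if (is.null(weights)) {
      br <- round(seq(0, len, length.out = k + 1))
    } else {
      wt <- weights[weights$chrom == ch, ]
      wt <- wt[order(wt$start), ]
      cum <- c(0, cumsum((wt$end - wt$start) * wt$weight))
      total <- cum[length(cum)]
      q <- seq(0, total, length.out = k + 1)
      # invert the piecewise-linear cumulative weight
      br <- purrr::map_dbl(q, function(target) {
        i <- findInterval(target, cum, rightmost.closed = TRUE)
        i <- min(max(i, 1), nrow(wt))
        if (wt$weight[i] <= 0) return(wt$start[i])
        wt$start[i] + (target - cum[i]) / wt$weight[i]
      })
      br[1] <- 0; br[k + 1] <- len
      br <- round(br)
    }
    br <- cummax(br)
    keep <- which(diff(br) > 0)
    tibble(chrom = ch, start = br[keep], end = br[keep + 1])
  })
}

#' Spike simulated CNVs into binned counts
#'
#' For each bin overlapped by a candidate region of copy number `N`, the
#' count is multiplied by the copy-number ratio `R = N/2` (length-weighted
#' when a region boundary falls inside the bin): `Ks = Kr * R`. Bins outside
#' every region are unchanged. Spiking the same regions into a cell and its
#' control makes the regions recoverable truth for the overlap-length
#' evaluation.
#'
#' @param counts Bin tibble with a `count` column (`chrom`, `start`, `end`,
#'   `count`).
#' @param regions A [cnv_regions()] tibble (`copy_number` column).
#' @param rounding `"round"` (deterministic, `round(Kr * R)`) or
#'   `"poisson"` (draws `Poisson(Kr * R)` for stochastic realism).
#' @param seed Seed, used only for `rounding = "poisson"`.
#' @return `counts` with the spiked `count` column and a `cn_truth` column.
#' @export
spike_in <- function(counts, regions, rounding = c("round", "poisson"),
                     seed = 1L) {
  rounding <- match.arg(rounding)
  regions <- cnv_regions(regions)
  ratio <- per_bin_copy_ratio(counts, regions)
  out <- as_tibble(counts)
  lambda <- out$count * ratio
  out$count <- if (rounding == "round") round(lambda) else
    withr::with_seed(seed, rpois(length(lambda), lambda))
  out$cn_truth <- 2 * ratio
  out
}

#' Normalize binned counts to copy ratios
#'
#' Divides per-bin counts by their mean so the genome-wide mean ratio is 1.
#' When bins carry GC content and `gc_correct = TRUE`, a smooth GC trend
#' (loess of count on GC) is divided out first, as in standard single-cell
#' CNV pipelines.
#'
#' @param counts Bin tibble with `count` (and optionally `gc`).
#' @param gc_correct Divide out the loess GC trend when GC is available.
#' @param span Loess span for the GC trend.
#' @return `counts` with an added `ratio` column (mean exactly 1).
#' @export
normalize_ratio <- function(counts, gc_correct = TRUE, span = 0.5) {
  out <- as_tibble(counts)
  if (sum(out$count) <= 0) abort("Total count must be positive.")
  val <- as.numeric(out$count)
  if (gc_correct && "gc" %in% names(out) && !anyNA(out$gc) && sd(out$gc) > 0) {
    fit <- loess(val ~ gc, data = tibble(val = val, gc = out$gc), span = span,
                 degree = 2, family = "symmetric")
    trend <- predict(fit, out$gc)
    trend <- pmax(trend, 1e-8 * mean(val))
    val <- val / (trend / mean(trend))
  }
  out$ratio <- val / mean(val)
  out
}

#' Segment per-bin copy ratios by circular binary segmentation
#'
#' Recursive circular binary segmentation: within each chromosome the arc
#' maximizing a two-sample t-like statistic is tested against a permutation
#' null; significant change-points are applied and segmentation recurses
#' into the pieces. The scan runs on log2 ratios (the standard scale for
#' copy-number segmentation: multiplicative amplification noise becomes
#' approximately Gaussian and symmetric, which keeps small outlier arcs
#' from dominating the permutation null), while reported segment means stay
#' on the ratio scale. Deterministic given `seed`.
#'
#' @param ratios Bin tibble with a `ratio` column (see [normalize_ratio()]).
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param min_width Minimum segment width in bins (default 2).
#' @param n_permutations Permutations per test (default 1000; the test stops
#'   early once significance is impossible).
#' @param seed Integer seed.
#' @return A `wga_segments` object: `$bins` (input plus `segment` id and
#'   `seg_ratio`, the segment mean ratio) and `$segments` (one row per
#'   segment with bin range, genomic span and `mean_ratio`).
#' @export
segment_ratios <- function(ratios, alpha = 0.01, min_width = 2,
                           n_permutations = 1000, seed = 1L) {
  bins <- as_tibble(ratios)
  if (!"ratio" %in% names(bins)) abort("`ratios` needs a `ratio` column.")
  if (nrow(bins) < min_width) abort("Fewer bins than `min_width`.")
  withr::with_seed(seed, {
    pieces <- split(seq_len(nrow(bins)), factor(bins$chrom, unique(bins$chrom)))
    seg_id <- integer(nrow(bins))
    next_id <- 0L
    log_ratio <- log2(pmax(bins$ratio, 1e-6))
    for (idx in pieces) {
      ends <- .cbs_segment_series(log_ratio[idx], alpha,
                                  as.integer(n_permutations),
                                  as.integer(min_width))
      starts <- c(1L, head(ends, -1) + 1L)
      for (s in seq_along(ends)) {
        next_id <- next_id + 1L
        seg_id[idx[starts[s]:ends[s]]] <- next_id
      }
    }
    bins$segment <- seg_id
    segments <- bins |>
      group_by(.data$segment) |>
      summarise(chrom = .data$chrom[1],
                start = min(.data$start), end = max(.data$end),
                start_bin = min(dplyr::cur_group_rows()),
                end_bin = max(dplyr::cur_group_rows()),
                n_bins = dplyr::n(),
                mean_ratio = mean(.data$ratio), .groups = "drop")
    bins$seg_ratio <- segments$mean_ratio[bins$segment]
    structure(list(bins = bins, segments = segments,
                   params = list(alpha = alpha, min_width = min_width,
                                 n_permutations = n_permutations, seed = seed)),
              class = "wga_segments")
  })
}

#' @export
print.wga_segments <- function(x, ...) {
  cat("<wga_segments> ", nrow(x$segments), " segment(s) over ",
      nrow(x$bins), " bins\n", sep = "")
  print(x$segments, n = 10)
  invisible(x)
}

#' @export
tidy.wga_segments <- function(x, ...) x$segments

#' @export
glance.wga_segments <- function(x, ...) {
  tibble(n_segments = nrow(x$segments), n_bins = nrow(x$bins),
         alpha = x$params$alpha,
         mode_anchored = !is.null(x$mode))
}

#' Anchor the modal segment ratio to copy number two
#'
#' The density of the per-bin segment ratios on autosomes is estimated by a
#' Gaussian kernel, and its mode is assigned copy number 2 (the dominant
#' ploidy state); every segment's copy number is then
#' `2 * mean_ratio / mode`. The assignment is invariant under any global
#' rescaling of the ratios. In genuinely ambiguous genomes (e.g. a
#' tetraploid-like bimodal density) the anchor follows the heavier mode.
#'
#' @param segments A `wga_segments` object.
#' @param autosomes Optional character vector of autosome labels; default
#'   uses all bins.
#' @return The `wga_segments` object with `copy_number` on `$segments` and
#'   `$bins`, and the anchoring `$mode`.
#' @export
mode_normalize <- function(segments, autosomes = NULL) {
  stopifnot(inherits(segments, "wga_segments"))
  vals <- segments$bins
  if (!is.null(autosomes)) vals <- filter(vals, .data$chrom %in% autosomes)
  if (nrow(vals) == 0) abort("No autosomal bins to anchor on.")
  v <- vals$seg_ratio
  m <- if (sd(v) < 1e-12) v[1] else {
    d <- density(v, n = 2048)
    d$x[which.max(d$y)]
  }
  if (!is.finite(m) || m <= 0) abort("Degenerate segment-ratio density.")
  segments$mode <- m
  segments$segments$copy_number <- 2 * segments$segments$mean_ratio / m
  segments$bins$copy_number <- 2 * segments$bins$seg_ratio / m
  segments
}

#' Call CNVs from a mode-anchored segment profile
#'
#' Segments with copy number at or above `gain` are gains, at or below
#' `loss` losses (midpoints between integer copy states by default);
#' adjacent same-direction segments are merged and only calls spanning at
#' least `min_length` bp are emitted.
#'
#' @param segments A mode-anchored `wga_segments` (see [mode_normalize()]).
#' @param min_length Minimum genomic span in bp (default 1 Mb).
#' @param gain,loss Copy-number thresholds (defaults 2.5 and 1.5).
#' @return A tibble of calls: `chrom`, `start`, `end`, `copy_number`
#'   (length-weighted across merged segments), `direction`.
#' @export
call_cnvs <- function(segments, min_length = 1e6, gain = 2.5, loss = 1.5) {
  stopifnot(inherits(segments, "wga_segments"))
  if (is.null(segments$segments$copy_number)) {
    abort("Profile must be mode-normalized first (see `mode_normalize()`).")
  }
  seg <- segments$segments |>
    mutate(direction = ifelse(.data$copy_number >= gain, "gain",
                              ifelse(.data$copy_number <= loss, "loss", "neutral"))) |>
    filter(.data$direction != "neutral")
  if (nrow(seg) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  copy_number = numeric(), direction = character()))
  }
  seg <- arrange(seg, .data$chrom, .data$start)
  # merge runs of adjacent same-direction segments (contiguous in bin space)
  seg$run <- cumsum(c(TRUE, !(seg$chrom[-1] == head(seg$chrom, -1) &
                                seg$direction[-1] == head(seg$direction, -1) &
                                seg$start_bin[-1] == head(seg$end_bin, -1) + 1)))
  seg |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              copy_number = sum(.data$copy_number * (.data$end - .data$start)) /
                sum(.data$end - .data$start),
              direction = .data$direction[1], .groups = "drop") |>
    select(-"run") |>
    filter(.data$end - .data$start >= min_length)
}

reduce_bp <- function(calls) {
  if (nrow(calls) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1, calls$end)))
}

#' Overlap-length evaluation of CNV calls
#'
#' The single-cell call set is scored against the control call set by total
#' genomic length: `L` is the total length of the cell's CNVs (>= 1 Mb),
#' `L_C` the control's, and `L_T` the length of their intersection. Then
#' `sensitivity = L_T / L_C` and `specificity = L_T / L` ("specificity" is
#' the field's name for this precision-like quantity and is kept).
#' Direction-agnostic by default; `require_direction = TRUE` intersects
#' gains with gains and losses with losses only.
#'
#' @param calls,control_calls CNV call tibbles (see [call_cnvs()]).
#' @param min_length Minimum span in bp; both sets are (re-)filtered.
#' @param require_direction Require matching gain/loss direction in the
#'   intersection.
#' @return A one-row tibble: `L`, `L_C`, `L_T`, `sensitivity`,
#'   `specificity` (undefined denominators yield `NA`, not 0).
#' @export
evaluate_cnvs <- function(calls, control_calls, min_length = 1e6,
                          require_direction = FALSE) {
  flt <- function(x) filter(as_tibble(x), .data$end - .data$start >= min_length)
  calls <- flt(calls); control_calls <- flt(control_calls)
  inter_len <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(0)
    sum(IRanges::width(GenomicRanges::intersect(reduce_bp(a), reduce_bp(b))))
  }
  L <- sum(calls$end - calls$start)
  L_C <- sum(control_calls$end - control_calls$start)
  L_T <- if (require_direction) {
    sum(purrr::map_dbl(c("gain", "loss"), function(d)
      inter_len(filter(calls, .data$direction == d),
                filter(control_calls, .data$direction == d))))
  } else inter_len(calls, control_calls)
  tibble(L = L, L_C = L_C, L_T = L_T,
         sensitivity = if (L_C > 0) L_T / L_C else NA_real_,
         specificity = if (L > 0) L_T / L else NA_real_)
}

#' Run the binned copy-number pipeline end to end
#'
#' Convenience wrapper: normalize counts to ratios, segment, anchor the
#' modal ratio to copy number two and call CNVs.
#'
#' @param counts Bin tibble with `count` (and optionally `gc`).
#' @param alpha,min_width,n_permutations,seed Segmentation parameters, see
#'   [segment_ratios()].
#' @param min_length,gain,loss Calling parameters, see [call_cnvs()].
#' @param gc_correct See [normalize_ratio()].
#' @param autosomes See [mode_normalize()].
#' @return A list with `segments` (`wga_segments`) and `calls` (tibble).
#' @export
cnv_pipeline <- function(counts, alpha = 0.01, min_width = 2,
                         n_permutations = 1000, seed = 1L,
                         min_length = 1e6, gain = 2.5, loss = 1.5,
                         gc_correct = TRUE, autosomes = NULL) {
  ratios <- normalize_ratio(counts, gc_correct = gc_correct)
  segs <- segment_ratios(ratios, alpha = alpha, min_width = min_width,
                         n_permutations = n_permutations, seed = seed)
  segs <- mode_normalize(segs, autosomes = autosomes)
  list(segments = segs,
       calls = call_cnvs(segs, min_length = min_length, gain = gain,
                         loss = loss))
}
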