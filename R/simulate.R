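#' Simulate a golden-control genotype set
#'
#' Draws a set of polymorphic control sites partitioned into the three
#' genotype categories used throughout the concordance analysis: `HOMref`
#' (both alleles equal the reference base), `HOMmut` (both alleles equal each
#' other but differ from the reference) and `HETref` (exactly one allele is
#' the reference). The default category proportions follow the composition
#' of a lymphoblastoid golden control restricted to a 2.5M SNP array
#' (HOMref : HOMmut : HETref roughly 1.585 : 0.270 : 0.351 million sites).
#'
#' @param genome A genome layout tibble, see [genome_layout()].
#' @param n_sites Number of control sites (>= 1).
#' @param category_proportions Length-3 non-negative vector over
#'   (HOMref, HOMmut, HETref) summing to 1.
#' @param seed Integer seed; all randomness flows from it.
#' @return A tibble with columns `chrom`, `pos` (1-based, strictly increasing
#'   within chromosome), `ref`, `a1`, `a2` (alleles, `a1 <= a2`), `category`.
#' @examples
#' gc <- simulate_golden_control(toy_genome(), n_sites = 100, seed = 1)
#' table(gc$category)
#' @export
simulate_golden_control <- function(genome,
                                    n_sites,
                                    category_proportions = c(HOMref = 1584649,
                                                             HOMmut = 270225,
                                                             HETref = 351490) / 2206364,
                                    seed = 1L) {
  stopifnot(is.data.frame(genome), n_sites >= 1)
  p <- as.numeric(category_proportions)
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`category_proportions` must be 3 non-negative values summing to 1.")
  }
  total_len <- sum(genome$length)
  if (total_len < 1) abort("Zero-length genome.")
  if (n_sites > total_len) abort("`n_sites` exceeds the number of available positions.")

  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    # sites spread over chromosomes proportionally to length
    n_per <- as.vector(rmultinom(1, n_sites, genome$length / total_len))
    while (any(n_per > genome$length)) {
      # extremely small toy genomes: push overflow onto the largest chromosome
      i <- which(n_per > genome$length)[1]
      excess <- n_per[i] - genome$length[i]
      n_per[i] <- genome$length[i]
      j <- which.max(genome$length - n_per)
      n_per[j] <- n_per[j] + excess
    }
    sites <- purrr::pmap_dfr(
      list(genome$chrom, genome$length, n_per),
      function(chrom, len, k) {
        if (k == 0L) return(tibble(chrom = character(), pos = integer()))
        tibble(chrom = chrom, pos = sort(sample.int(len, k)))
      }
    )
    n <- nrow(sites)
    category <- sample(c("HOMref", "HOMmut", "HETref"), n,
                       replace = TRUE, prob = p)
    ref <- sample(bases, n, replace = TRUE)
    # one alternative allele per site, never equal to the reference
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    a1 <- ifelse(category == "HOMmut", alt, ref)
    a2 <- ifelse(category == "HOMref", ref, alt)
    out <- sites
    out$ref <- ref
    out$a1 <- pmin(a1, a2)
    out$a2 <- pmax(a1, a2)
    out$category <- category
    out
  })
}

sort_alleles <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  tibble(a1 = lo, a2 = hi)
}

#' Simulate single-cell genotype calls from a golden control
#'
#' Corrupts a golden control with the three artifact processes of
#' whole-genome amplification: incomplete coverage (each site is callable
#' with probability `site_coverage`), allele drop-out at covered heterozygous
#' sites (one allele is lost and the call becomes homozygous for the retained
#' allele) and false-positive allele gain (a spurious substitution replaces
#' one allele with a base not present in the true genotype, so every FP event
#' is discordant with the control). ADO and FP are mutually exclusive per
#' site, which keeps truth labels and estimator counts in exact
#' correspondence.
#'
#' @param control A golden control tibble from [simulate_golden_control()].
#' @param profile A [method_profile()].
#' @param seed Integer seed.
#' @param ado_mode `"symmetric"` (either allele retained with probability
#'   1/2, the default) or `"ref_biased"` (the reference allele is retained,
#'   i.e. the alternative allele fails to amplify).
#' @return A tibble of covered sites only, with columns `chrom`, `pos`,
#'   `a1`, `a2` and `truth` in `{"faithful","ADO","FP"}`. Control sites
#'   absent from the result were uncovered.
#' @export
simulate_single_cell_calls <- function(control, profile, seed = 1L,
                                       ado_mode = c("symmetric", "ref_biased")) {
  stopifnot(is.data.frame(control), inherits(profile, "method_profile"))
  ado_mode <- match.arg(ado_mode)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    n <- nrow(control)
    covered <- runif(n) < profile$site_coverage
    calls <- control[covered, c("chrom", "pos", "a1", "a2", "category")]
    m <- nrow(calls)
    truth <- rep("faithful", m)

    is_het <- calls$category == "HETref"
    ado <- is_het & runif(m) < profile$ado_rate
    if (any(ado)) {
      keep_ref <- if (ado_mode == "ref_biased") rep(TRUE, sum(ado)) else
        runif(sum(ado)) < 0.5
      ref_allele <- control$ref[covered][ado]
      alt_allele <- ifelse(calls$a1[ado] == ref_allele,
                           calls$a2[ado], calls$a1[ado])
      kept <- ifelse(keep_ref, ref_allele, alt_allele)
      calls$a1[ado] <- kept
      calls$a2[ado] <- kept
      truth[ado] <- "ADO"
    }

    fp <- !ado & runif(m) < profile$fp_rate
    if (any(fp)) {
      idx <- which(fp)
      for (i in idx) {
        present <- unique(c(calls$a1[i], calls$a2[i]))
        new_base <- sample(setdiff(bases, present), 1)
        if (runif(1) < 0.5) calls$a1[i] <- new_base else calls$a2[i] <- new_base
      }
      srt <- sort_alleles(calls$a1[idx], calls$a2[idx])
      calls$a1[idx] <- srt$a1
      calls$a2[idx] <- srt$a2
      truth[fp] <- "FP"
    }

    calls$category <- NULL
    calls$truth <- truth
    calls
  })
}

#' Copy-number truth regions
#'
#' Validates a table of non-overlapping copy-number regions (BED-style
#' 0-based half-open coordinates) with integer copy number `N`; the rest of
#' the genome is implicitly diploid. `simulate_cnv_regions()` places
#' non-overlapping regions of the requested length range at random.
#'
#' @param regions A data frame with columns `chrom`, `start`, `end`,
#'   `copy_number`.
#' @return A validated tibble of regions sorted by chromosome and start.
#' @export
cnv_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(regions)))
  out <- as_tibble(regions) |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end),
           copy_number = as.numeric(.data$copy_number)) |>
    arrange(.data$chrom, .data$start)
  if (any(out$end <= out$start)) abort("Regions must satisfy end > start.")
  if (any(out$copy_number < 0) ||
      any(out$copy_number != round(out$copy_number))) {
    abort("`copy_number` must be a non-negative integer.")
  }
  overlap <- out |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < head(.data$end, -1)), .groups = "drop")
  if (any(overlap$bad)) abort("Regions overlap within a chromosome.")
  out
}

#' @param genome Genome layout.
#' @param n_regions Number of regions to place.
#' @param length_range Range of region lengths in bp.
#' @param copy_numbers Integer copy numbers to sample from (diploid elsewhere).
#' @param seed Integer seed.
#' @rdname cnv_regions
#' @export
simulate_cnv_regions <- function(genome, n_regions = 8,
                                 length_range = c(5e6, 2e7),
                                 copy_numbers = c(0, 1, 3, 4),
                                 seed = 1L) {
  withr::with_seed(seed, {
    placed <- tibble(chrom = character(), start = numeric(), end = numeric(),
                     copy_number = numeric())
    attempts <- 0
    while (nrow(placed) < n_regions && attempts < 50 * n_regions) {
      attempts <- attempts + 1
      len <- round(runif(1, length_range[1], length_range[2]))
      ok_chrom <- genome[genome$length > len, ]
      if (nrow(ok_chrom) == 0) break
      row <- ok_chrom[sample.int(nrow(ok_chrom), 1), ]
      start <- floor(runif(1, 0, row$length - len))
      cand <- tibble(chrom = row$chrom, start = start, end = start + len,
                     copy_number = sample(copy_numbers, 1))
      same <- placed[placed$chrom == cand$chrom, ]
      if (nrow(same) == 0 ||
          all(cand$end <= same$start | cand$start >= same$end)) {
        placed <- bind_rows(placed, cand)
      }
    }
    cnv_regions(placed)
  })
}

per_bin_copy_ratio <- function(bins, truth) {
  ratio <- rep(1, nrow(bins))
  if (is.null(truth) || nrow(truth) == 0) return(ratio)
  gb <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start + 1, bins$end))
  gt <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  hits <- GenomicRanges::findOverlaps(gb, gt)
  if (length(hits) == 0) return(ratio)
  ov <- IRanges::width(IRanges::pintersect(gb[S4Vectors::queryHits(hits)],
                                           gt[S4Vectors::subjectHits(hits)]))
  df <- tibble(bin = S4Vectors::queryHits(hits),
               r = truth$copy_number[S4Vectors::subjectHits(hits)] / 2,
               w = ov) |>
    group_by(.data$bin) |>
    summarise(covered = sum(.data$w),
              rsum = sum(.data$r * .data$w), .groups = "drop")
  widths <- bins$end[df$bin] - bins$start[df$bin]
  # length-weighted mix of region ratio and diploid background
  ratio[df$bin] <- (df$rsum + (widths - df$covered) * 1) / widths
  ratio
}

#' Simulate over-dispersed per-bin read counts
#'
#' Per-bin counts are Poisson draws whose intensity is the product of the
#' target mean, a per-bin multiplicative amplification factor (log-normal
#' with unit median and log-s.d. `profile$bin_dispersion`) and the local
#' copy-number ratio `N/2` from the truth profile (length-weighted across a
#' bin when a region boundary falls inside it). An optional linear GC
#' coupling can be imposed to exercise GC correction.
#'
#' @param bins A bin scheme tibble from [make_bins()] (columns `chrom`,
#'   `start`, `end`, optionally `gc`).
#' @param truth A [cnv_regions()] tibble or `NULL` for a flat diploid genome.
#' @param profile A [method_profile()]; only `bin_dispersion` is used.
#' @param mean_count_per_bin Target mean count in a diploid bin (> 0).
#' @param gc_coefficient Optional linear GC bias slope: intensity is
#'   multiplied by `1 + gc_coefficient * gc` (requires a `gc` column).
#' @param seed Integer seed.
#' @return The bin tibble plus columns `count` and `cn_truth` (the
#'   length-weighted truth copy number of the bin).
#' @export
simulate_binned_counts <- function(bins, truth = NULL, profile = wga_profiles()$bulk,
                                   mean_count_per_bin = 600,
                                   gc_coefficient = 0, seed = 1L) {
  stopifnot(is.data.frame(bins), nrow(bins) > 0, mean_count_per_bin > 0)
  if (profile$bin_dispersion < 0) abort("Negative dispersion.")
  ratio <- per_bin_copy_ratio(bins, truth)
  n <- nrow(bins)
  withr::with_seed(seed, {
    amp <- rlnorm(n, meanlog = 0, sdlog = profile$bin_dispersion)
    lambda <- mean_count_per_bin * amp * ratio
    if (gc_coefficient != 0) {
      if (!"gc" %in% names(bins)) abort("GC coupling requested but bins have no `gc`.")
      lambda <- lambda * pmax(0, 1 + gc_coefficient * bins$gc)
    }
    out <- as_tibble(bins)
    out$count <- rpois(n, lambda)
    out$cn_truth <- 2 * ratio
    out
  })
}

canonicalize_breakpoints <- function(bp) {
  flip <- (bp$chrom_a == bp$chrom_b & bp$pos_a > bp$pos_b) |
    (bp$chrom_a != bp$chrom_b & bp$chrom_a > bp$chrom_b)
  tmp_c <- bp$chrom_a[flip]; tmp_p <- bp$pos_a[flip]
  bp$chrom_a[flip] <- bp$chrom_b[flip]; bp$pos_a[flip] <- bp$pos_b[flip]
  bp$chrom_b[flip] <- tmp_c; bp$pos_b[flip] <- tmp_p
  bp
}

#' Simulate a plausible set of true structural-variant breakpoints
#'
#' @param genome Genome layout.
#' @param n Number of breakpoints.
#' @param type_mix Named proportions over ITX, CTX, DEL, INS, INV.
#' @param span_range Span range in bp for same-chromosome events.
#' @param seed Integer seed.
#' @return A breakpoint tibble (`chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `type`), canonicalized so `pos_a <= pos_b` on a chromosome and
#'   `chrom_a <= chrom_b` across chromosomes.
#' @export
simulate_true_breakpoints <- function(genome, n = 100,
                                      type_mix = c(ITX = 0.3, CTX = 0.1,
                                                   DEL = 0.3, INS = 0.15,
                                                   INV = 0.15),
                                      span_range = c(2e5, 5e6),
                                      seed = 1L) {
  withr::with_seed(seed, {
    types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
    chrom_a <- sample(genome$chrom, n, replace = TRUE, prob = genome$length)
    len_a <- genome$length[match(chrom_a, genome$chrom)]
    is_ctx <- types == "CTX"
    chrom_b <- chrom_a
    if (any(is_ctx)) {
      if (nrow(genome) < 2) abort("CTX breakpoints need >= 2 chromosomes.")
      chrom_b[is_ctx] <- purrr::map_chr(chrom_a[is_ctx], function(ca)
        sample(setdiff(genome$chrom, ca), 1))
    }
    span <- round(runif(n, span_range[1], span_range[2]))
    pos_a <- floor(runif(n, 1, pmax(2, len_a - span)))
    len_b <- genome$length[match(chrom_b, genome$chrom)]
    pos_b <- ifelse(is_ctx, floor(runif(n, 1, len_b)),
                    pmin(pos_a + span, len_a))
    canonicalize_breakpoints(
      tibble(chrom_a = chrom_a, pos_a = pos_a,
             chrom_b = chrom_b, pos_b = pos_b, type = types))
  })
}

#' Simulate single-cell breakpoints with injected WGA chimeras
#'
#' The control set is the true breakpoints as given. The single-cell set is
#' the true breakpoints with both ends jittered uniformly within
#' `+/- jitter` bp (so they remain matchable under the 100 bp rule), plus
#' `Poisson(chimera_rate * n_true)` injected chimeric junctions. Injected
#' chimera types follow `profile$chimera_type_mix`; same-chromosome chimeras
#' have an exponential end-to-end distance with mean
#' `profile$chimera_itx_length_scale` (short-range, as expected when
#' neighbouring amplicons join on the same chromosome), while CTX chimeras
#' connect two uniform positions on different chromosomes.
#'
#' @param true_breakpoints A breakpoint tibble (see
#'   [simulate_true_breakpoints()]).
#' @param profile A [method_profile()].
#' @param genome Genome layout.
#' @param jitter Maximum absolute per-end jitter in bp (default 50).
#' @param seed Integer seed.
#' @return A list with `control` (tibble) and `cell` (tibble with a `truth`
#'   column in `{"true","chimera"}`).
#' @export
simulate_breakpoints <- function(true_breakpoints, profile, genome,
                                 jitter = 50, seed = 1L) {
  stopifnot(is.data.frame(true_breakpoints), inherits(profile, "method_profile"))
  withr::with_seed(seed, {
    control <- canonicalize_breakpoints(as_tibble(true_breakpoints))
    n_true <- nrow(control)
    cell <- control
    lens <- genome$length[match(cell$chrom_a, genome$chrom)]
    lens_b <- genome$length[match(cell$chrom_b, genome$chrom)]
    cell$pos_a <- pmin(pmax(1, cell$pos_a +
                              sample(seq(-jitter, jitter), n_true, TRUE)), lens)
    cell$pos_b <- pmin(pmax(1, cell$pos_b +
                              sample(seq(-jitter, jitter), n_true, TRUE)), lens_b)
    cell$truth <- "true"

    n_chim <- rpois(1, profile$chimera_rate * n_true)
    if (n_chim > 0) {
      types <- sample(names(profile$chimera_type_mix), n_chim, replace = TRUE,
                      prob = profile$chimera_type_mix)
      chrom_a <- sample(genome$chrom, n_chim, replace = TRUE,
                        prob = genome$length)
      len_a <- genome$length[match(chrom_a, genome$chrom)]
      is_ctx <- types == "CTX"
      chrom_b <- chrom_a
      if (any(is_ctx) && nrow(genome) > 1) {
        chrom_b[is_ctx] <- purrr::map_chr(chrom_a[is_ctx], function(ca)
          sample(setdiff(genome$chrom, ca), 1))
      }
      span <- pmax(1, round(rexp(n_chim, 1 / profile$chimera_itx_length_scale)))
      pos_a <- floor(runif(n_chim, 1, len_a))
      len_b <- genome$length[match(chrom_b, genome$chrom)]
      pos_b <- ifelse(is_ctx, floor(runif(n_chim, 1, len_b)),
                      pmin(pos_a + span, len_a))
      chim <- canonicalize_breakpoints(
        tibble(chrom_a = chrom_a, pos_a = pos_a,
               chrom_b = chrom_b, pos_b = pos_b, type = types))
      chim$truth <- "chimera"
      cell <- bind_rows(cell, chim)
    }
    cell <- canonicalize_breakpoints(cell)
    list(control = control, cell = cell)
  })
}

#' Simulate per-window depth tracks
#'
#' Windows tile each chromosome at `window_width`; per-window mean depth is
#' `mean_depth` times a log-normal amplification factor with log-s.d.
#' `dispersion` (unit median). A synthetic GC fraction per window is drawn
#' from a Beta distribution centred near 0.41 (genome-wide GC).
#'
#' @param genome Genome layout.
#' @param window_width Window width in bp (default 100 kb).
#' @param mean_depth Genome-wide mean depth.
#' @param dispersion Log-scale s.d. of the per-window amplification factor.
#' @param seed Integer seed.
#' @return A depth-track tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `depth`, `gc`.
#' @export
simulate_depth_track <- function(genome, window_width = 1e5, mean_depth = 30,
                                 dispersion = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    win <- purrr::pmap_dfr(list(genome$chrom, genome$length),
                           function(chrom, len) {
      starts <- seq(0, len - 1, by = window_width)
      tibble(chrom = chrom, start = starts,
             end = pmin(starts + window_width, len))
    })
    n <- nrow(win)
    win$depth <- mean_depth * rlnorm(n, 0, dispersion)
    win$gc <- stats::rbeta(n, 41, 59)
    win
  })
}

#' Simulate mapped/duplicate read flags
#'
#' @param n_reads Number of reads.
#' @param mapping_rate Probability a read maps.
#' @param duplication_rate Probability a mapped read is a duplicate.
#' @param seed Integer seed.
#' @return A tibble with logical columns `mapped` and `duplicate`.
#' @export
simulate_read_flags <- function(n_reads, mapping_rate = 0.95,
                                duplication_rate = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    mapped <- runif(n_reads) < mapping_rate
    duplicate <- mapped & runif(n_reads) < duplication_rate
    tibble(mapped = mapped, duplicate = duplicate)
  })
}
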