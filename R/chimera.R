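#' Classify single-cell breakpoints as true variants or WGA chimeras
#'
#' A single-cell breakpoint is "true" when some control (bulk) breakpoint
#' has the same type (when `same_type`), the same unordered chromosome
#' pairing, and lies within `max_distance` bp (default 100). By default both
#' ends must be within the threshold; `both_ends = FALSE` relaxes the rule
#' to at least one end. Matching is greedy one-to-one: candidate pairs are
#' taken in order of increasing total end distance (ties broken by genomic
#' order) and each control breakpoint validates at most one single-cell
#' breakpoint. Everything unmatched is a chimera.
#'
#' @param cell Single-cell breakpoint tibble: `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `type` in `{INS, DEL, INV, ITX, CTX}`.
#' @param control Control breakpoint tibble (same columns).
#' @param max_distance Per-end distance threshold in bp (default 100).
#' @param same_type Require matching type (default `TRUE`).
#' @param both_ends Require both ends within the threshold (default `TRUE`).
#' @return The `cell` tibble with added columns `label` in
#'   `{"true","chimera"}` and `matched_control` (control row index or `NA`).
#' @export
match_breakpoints <- function(cell, control, max_distance = 100,
                              same_type = TRUE, both_ends = TRUE) {
  if (max_distance < 0) abort("`max_distance` must be >= 0.")
  cell <- canonicalize_breakpoints(as_tibble(cell))
  control <- canonicalize_breakpoints(as_tibble(control))
  n <- nrow(cell)
  cell$label <- rep("chimera", n)
  cell$matched_control <- NA_integer_
  if (n == 0 || nrow(control) == 0) return(cell)

  key_cell <- paste(cell$chrom_a, cell$chrom_b,
                    if (same_type) cell$type else "")
  key_ctl <- paste(control$chrom_a, control$chrom_b,
                   if (same_type) control$type else "")
  cand <- purrr::map_dfr(seq_len(n), function(i) {
    j <- which(key_ctl == key_cell[i])
    if (length(j) == 0) return(NULL)
    da <- abs(control$pos_a[j] - cell$pos_a[i])
    db <- abs(control$pos_b[j] - cell$pos_b[i])
    ok <- if (both_ends) da <= max_distance & db <= max_distance else
      da <= max_distance | db <= max_distance
    if (!any(ok)) return(NULL)
    tibble(cell = i, ctl = j[ok], dist = (da + db)[ok])
  })
  if (nrow(cand) == 0) return(cell)
  cand$chrom <- cell$chrom_a[cand$cell]
  cand$pos <- cell$pos_a[cand$cell]
  cand <- arrange(cand, .data$dist, .data$chrom, .data$pos, .data$cell,
                  .data$ctl)
  used_ctl <- logical(nrow(control))
  used_cell <- logical(n)
  for (r in seq_len(nrow(cand))) {
    i <- cand$cell[r]; j <- cand$ctl[r]
    if (!used_cell[i] && !used_ctl[j]) {
      used_cell[i] <- TRUE; used_ctl[j] <- TRUE
      cell$label[i] <- "true"
      cell$matched_control[i] <- j
    }
  }
  cell
}

bp_types <- c("ITX", "CTX", "DEL", "INS", "INV")

#' Chimera type fractions
#'
#' Percentage of each breakpoint type among chimera-labelled breakpoints
#' (the short-range intra-chromosomal ITX type dominates in MDA data).
#' Returns an empty tibble when there are no chimeras.
#'
#' @param labeled A labelled breakpoint tibble from [match_breakpoints()]
#'   (or any tibble with `type` and `label` columns).
#' @return A tibble with columns `type`, `n`, `fraction`, `percent` over
#'   the five types (fractions sum to 1).
#' @export
chimera_type_fractions <- function(labeled) {
  chim <- filter(as_tibble(labeled), .data$label == "chimera")
  if (nrow(chim) == 0) {
    return(tibble(type = character(), n = integer(),
                  fraction = numeric(), percent = numeric()))
  }
  tab <- table(factor(chim$type, bp_types))
  tibble(type = bp_types, n = as.integer(tab)) |>
    mutate(fraction = .data$n / sum(.data$n),
           percent = 100 * .data$fraction)
}

#' Compare ITX span distributions of shared versus chimeric breakpoints
#'
#' Mann-Whitney-Wilcoxon comparison of the end-to-end spans of ITX
#' breakpoints shared with the bulk control against those unique to the
#' single cell (chimeras); chimeric ITX junctions are expected to be
#' stochastically shorter, arising from neighbouring amplicons.
#'
#' @param shared_spans,chimera_spans Numeric span vectors in bp (>= 1 value
#'   each).
#' @param alternative Test alternative for `shared` versus `chimera`
#'   (default `"two.sided"`; use `"greater"` for the one-sided
#'   shorter-chimera direction).
#' @return A one-row tibble: `statistic`, `p_value`, `method`,
#'   `alternative`, `median_shared`, `median_chimera`.
#' @export
itx_length_compare <- function(shared_spans, chimera_spans,
                               alternative = "two.sided") {
  if (length(shared_spans) == 0 || length(chimera_spans) == 0) {
    abort("Both span groups must be nonempty.")
  }
  res <- mann_whitney(shared_spans, chimera_spans, alternative = alternative)
  res$median_shared <- median(shared_spans)
  res$median_chimera <- median(chimera_spans)
  res[, c("statistic", "p_value", "method", "alternative",
          "median_shared", "median_chimera")]
}

#' Breakpoint spans
#'
#' End-to-end distance of same-chromosome breakpoints; `NA` for CTX.
#'
#' @param bp Breakpoint tibble.
#' @return Numeric vector of spans in bp.
#' @export
breakpoint_span <- function(bp) {
  ifelse(bp$chrom_a == bp$chrom_b, abs(bp$pos_b - bp$pos_a), NA_real_)
}
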