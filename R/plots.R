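#' Plot a segmented copy-number profile
#'
#' Per-bin ratios as points with segment means overlaid; when the profile
#' is mode-anchored the y axis is copy number.
#'
#' @param object A `wga_segments` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wga_segments <- function(object, ...) {
  bins <- object$bins
  bins$index <- seq_len(nrow(bins))
  anchored <- "copy_number" %in% names(bins)
  bins$y <- if (anchored) 2 * bins$ratio / object$mode else bins$ratio
  bins$yseg <- if (anchored) bins$copy_number else bins$seg_ratio
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y, colour = .data$chrom),
                        size = 0.4, alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$yseg), linewidth = 0.7) +
    ggplot2::labs(x = "bin", y = if (anchored) "copy number" else "ratio") +
    ggplot2::theme_minimal()
}

#' Plot normalized depth distributions against a Poisson reference
#'
#' @param track A depth track with `norm_depth` (see [normalized_depth()]).
#' @param reference Optional [poisson_reference()] tibble.
#' @return A ggplot.
#' @export
plot_normalized_depth <- function(track, reference = NULL) {
  df <- tibble(norm = track$norm_depth, source = "observed")
  if (!is.null(reference)) {
    df <- bind_rows(df, tibble(norm = reference$norm, source = "Poisson"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$norm, colour = .data$source)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "normalized depth", y = "density") +
    ggplot2::theme_minimal()
}

#' Bar chart of chimera type fractions
#'
#' @param fractions Output of [chimera_type_fractions()].
#' @return A ggplot.
#' @export
plot_chimera_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$type, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chimera type", y = "percent of chimeras") +
    ggplot2::theme_minimal()
}

#' Heatmap of a genotype concordance matrix
#'
#' @param object A `wga_concordance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wga_concordance <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$control_category,
                               y = .data$sc_category,
                               fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~share, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "golden control", y = "single cell") +
    ggplot2::theme_minimal()
}
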