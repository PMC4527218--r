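#' Describe a genome as chromosome lengths
#'
#' A genome layout is the minimal coordinate system the simulators and the
#' binning code need: one row per chromosome with its length in bp. Layouts
#' are deliberately tiny tibbles so synthetic genomes scale from kilobases
#' (unit tests) to gigabases (full-size simulations) without any change of
#' representation.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome labels), or a data frame with columns
#'   `chrom` and `length`.
#' @return A tibble with columns `chrom` (character) and `length` (double).
#' @examples
#' genome_layout(c(chr1 = 5e6, chr2 = 3e6))
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(lengths)))
    out <- tibble(chrom = as.character(lengths$chrom),
                  length = as.numeric(lengths$length))
  } else {
    if (is.null(names(lengths)) || any(names(lengths) == "")) {
      abort("`lengths` must be a named vector (names are chromosome labels).")
    }
    out <- tibble(chrom = names(lengths), length = as.numeric(lengths))
  }
  if (nrow(out) == 0L || any(out$length <= 0)) {
    abort("Genome layout needs at least one chromosome of positive length.")
  }
  if (anyDuplicated(out$chrom)) abort("Duplicated chromosome labels.")
  out
}

#' Toy genome layouts for examples and tests
#'
#' `toy_genome()` builds an autosome-style layout of `n_chrom` equal-length
#' chromosomes; `human_like_genome()` is a 22-autosome layout scaled to a
#' given total size, with lengths decaying roughly like the human karyotype.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
toy_genome <- function(n_chrom = 2, chrom_length = 1e7) {
  genome_layout(setNames(rep(chrom_length, n_chrom),
                         paste0("chr", seq_len(n_chrom))))
}

#' @param total_length Total genome size in bp to distribute over 22 autosomes.
#' @rdname toy_genome
#' @export
human_like_genome <- function(total_length = 3e9) {
  # Lengths decay ~linearly from chr1 to chr22, as in the human karyotype.
  w <- seq(2.4, 0.5, length.out = 22)
  genome_layout(setNames(round(total_length * w / sum(w)), paste0("chr", 1:22)))
}

chrom_order <- function(chrom, layout) {
  factor(chrom, levels = layout$chrom)
}
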