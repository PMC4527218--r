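#' Read and write genotype tables
#'
#' Genotype tables are 1-based site lists with an unordered allele pair:
#' columns `chrom`, `pos`, `ref`, `a1`, `a2`, plus optional `category`,
#' `callable` or `truth`. `read_genotypes()` also accepts VCF (`.vcf` /
#' `.vcf.gz`, GT field against REF/ALT; requires the vcfR package);
#' `write_genotypes_vcf()` emits a minimal GT-only VCF.
#'
#' @param path File path (TSV, or VCF for `read_genotypes()`).
#' @return A genotype tibble.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("Reading VCF requires the vcfR package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
    alleles <- strsplit(gsub("\\|", "/", gt), "/")
    allele_mat <- purrr::map2_dfr(alleles, seq_along(alleles), function(a, i) {
      opts <- c(fix$REF[i], strsplit(fix$ALT[i], ",")[[1]])
      tibble(a1 = opts[as.integer(a[1]) + 1], a2 = opts[as.integer(a[2]) + 1])
    })
    out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
                  a1 = pmin(allele_mat$a1, allele_mat$a2),
                  a2 = pmax(allele_mat$a1, allele_mat$a2))
    return(out)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param x Genotype tibble.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @param sample_name Sample column name for the VCF.
#' @rdname read_genotypes
#' @export
write_genotypes_vcf <- function(x, path, sample_name = "sample") {
  x <- as_tibble(x)
  alt <- ifelse(x$a1 == x$ref & x$a2 == x$ref, ".",
                ifelse(x$a1 == x$ref, x$a2,
                       ifelse(x$a2 == x$ref, x$a1,
                              ifelse(x$a1 == x$a2, x$a1,
                                     paste(x$a1, x$a2, sep = ",")))))
  idx <- function(a) ifelse(a == x$ref, 0L,
                            ifelse(a == sub(",.*", "", alt), 1L, 2L))
  gt <- paste(idx(x$a1), idx(x$a2), sep = "/")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample_name),
             paste(x$chrom, x$pos, ".", x$ref, alt, ".", "PASS", ".", "GT",
                   gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write interval tables (BED-style, 0-based half-open)
#'
#' Copy-number truth regions are written as `chrom`, `start`, `end`,
#' `copy_number`; generic interval tables keep whatever extra columns they
#' carry.
#'
#' @param path File path.
#' @param x Interval tibble.
#' @return A tibble (readers) or `path` invisibly (writers).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_intervals
#' @export
write_intervals <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write breakpoint tables (BEDPE-like TSV)
#'
#' Columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`, `type` (one of INS, DEL,
#' INV, ITX, CTX) plus optional `label`/`truth`.
#'
#' @param path File path.
#' @param x Breakpoint tibble.
#' @export
read_breakpoints <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  bad <- setdiff(unique(out$type), c("INS", "DEL", "INV", "ITX", "CTX"))
  if (length(bad)) abort(paste0("Unknown breakpoint type(s): ",
                                paste(bad, collapse = ", ")))
  canonicalize_breakpoints(out)
}

#' @rdname read_breakpoints
#' @export
write_breakpoints <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
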