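#' Parameter profile of a whole-genome-amplification method
#'
#' A method profile collects the artifact rates a WGA chemistry imprints on
#' single-cell sequencing data: allele drop-out (ADO) at heterozygous sites,
#' spurious-allele false positives (FP), incomplete site coverage,
#' over-dispersion of per-bin read counts (the log-scale s.d. of a
#' multiplicative per-bin amplification factor), read duplication, and the
#' rate, type mix and intra-chromosomal length scale of chimeric junctions.
#' Profiles parameterize the synthetic-data generators; the estimators then
#' try to recover these rates.
#'
#' @param name Method label.
#' @param ado_rate Probability in \[0,1\] that a covered heterozygous site
#'   loses one allele during amplification.
#' @param fp_rate Probability in \[0,1\] per covered site of gaining a
#'   spurious allele substitution.
#' @param site_coverage Probability in \[0,1\] that a control site is callable
#'   in the amplified cell.
#' @param bin_dispersion Positive log-scale s.d. of the per-bin amplification
#'   factor (0 recovers pure Poisson counting noise).
#' @param duplication_rate Probability in \[0,1\] that a mapped read is a
#'   duplicate.
#' @param chimera_rate Expected number of chimeric junctions injected per true
#'   breakpoint.
#' @param chimera_type_mix Named proportions over the five breakpoint types
#'   `ITX`, `CTX`, `DEL`, `INS`, `INV`; normalized to sum to 1.
#' @param chimera_itx_length_scale Mean end-to-end distance (bp) of injected
#'   intra-chromosomal (ITX) chimeras; chimeras are short-range because they
#'   arise from neighboring amplicons joining on the same chromosome.
#' @return An object of class `method_profile` (a named list).
#' @seealso [wga_profiles()] for bundled presets.
#' @examples
#' method_profile("noisy", ado_rate = 0.3, fp_rate = 1e-4)
#' @export
method_profile <- function(name = "custom",
                           ado_rate = 0,
                           fp_rate = 0,
                           site_coverage = 1,
                           bin_dispersion = 1e-8,
                           duplication_rate = 0,
                           chimera_rate = 0,
                           chimera_type_mix = c(ITX = 0.8208, CTX = 0.0113,
                                                DEL = 0.0809, INS = 0.0507,
                                                INV = 0.0368),
                           chimera_itx_length_scale = 1e4) {
  probs <- c(ado_rate = ado_rate, fp_rate = fp_rate,
             site_coverage = site_coverage, duplication_rate = duplication_rate)
  if (any(probs < 0 | probs > 1)) {
    abort(paste0("Probabilities must lie in [0,1]: ",
                 paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")))
  }
  if (!is.numeric(bin_dispersion) || bin_dispersion <= 0) {
    abort("`bin_dispersion` must be > 0 (use a tiny value for the Poisson limit).")
  }
  if (chimera_rate < 0) abort("`chimera_rate` must be >= 0.")
  if (chimera_itx_length_scale <= 0) abort("`chimera_itx_length_scale` must be > 0.")
  bp_types <- c("ITX", "CTX", "DEL", "INS", "INV")
  if (is.null(names(chimera_type_mix)) ||
      !setequal(names(chimera_type_mix), bp_types)) {
    abort("`chimera_type_mix` must be named over ITX, CTX, DEL, INS, INV.")
  }
  if (any(chimera_type_mix < 0) || sum(chimera_type_mix) <= 0) {
    abort("`chimera_type_mix` proportions must be non-negative and not all zero.")
  }
  mix <- chimera_type_mix[bp_types] / sum(chimera_type_mix)
  structure(list(name = name,
                 ado_rate = ado_rate,
                 fp_rate = fp_rate,
                 site_coverage = site_coverage,
                 bin_dispersion = bin_dispersion,
                 duplication_rate = duplication_rate,
                 chimera_rate = chimera_rate,
                 chimera_type_mix = mix,
                 chimera_itx_length_scale = chimera_itx_length_scale),
            class = "method_profile")
}

#' @export
print.method_profile <- function(x, ...) {
  cat("<method_profile> ", x$name, "\n", sep = "")
  cat(sprintf("  ADO %.4g | FP %.3g | site coverage %.3g | bin dispersion %.3g\n",
              x$ado_rate, x$fp_rate, x$site_coverage, x$bin_dispersion))
  cat(sprintf("  duplication %.3g | chimera rate %.3g | ITX scale %.3g bp\n",
              x$duplication_rate, x$chimera_rate, x$chimera_itx_length_scale))
  cat("  chimera mix:",
      paste(sprintf("%s %.3f", names(x$chimera_type_mix), x$chimera_type_mix),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bundled WGA method presets
#'
#' Presets sketching the three amplification strategies the package is built
#' to compare, plus an unamplified bulk control. Printed artifact rates
#' (ADO, FP, site coverage, the MDA chimera type mix) follow the reported
#' per-method measurements; dispersion, duplication and chimera-rate values
#' encode the reported qualitative ordering (DOP-PCR most uniform but
#' duplicate-heavy, MDA least uniform and chimera-prone, MALBAC in between)
#' and are documented in the methods vignette.
#'
#' @return A named list of [method_profile()] objects:
#'   `mda2`, `malbac`, `dop1`, `bulk`.
#' @export
wga_profiles <- function() {
  list(
    mda2 = method_profile(
      name = "MDA-2", ado_rate = 0.1247, fp_rate = 5.31e-5,
      site_coverage = 0.8457, bin_dispersion = 0.8, duplication_rate = 0.05,
      chimera_rate = 5,
      chimera_itx_length_scale = 1e4),
    malbac = method_profile(
      name = "MALBAC", ado_rate = 0.21, fp_rate = 4e-5,
      site_coverage = 0.5187, bin_dispersion = 0.35, duplication_rate = 0.15,
      chimera_rate = 1,
      chimera_itx_length_scale = 1e4),
    dop1 = method_profile(
      name = "DOP-1", ado_rate = 0.30, fp_rate = 1e-4,
      site_coverage = 0.06, bin_dispersion = 0.15, duplication_rate = 0.70,
      chimera_rate = 0.5,
      chimera_itx_length_scale = 1e4),
    bulk = method_profile(
      name = "bulk", ado_rate = 0, fp_rate = 0,
      site_coverage = 0.99, bin_dispersion = 0.02, duplication_rate = 0.02,
      chimera_rate = 0)
  )
}

#' Read and write method profiles as YAML
#'
#' @param profile A [method_profile()].
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [method_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "method_profile"))
  x <- unclass(profile)
  x$chimera_type_mix <- as.list(x$chimera_type_mix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- yaml::read_yaml(path)
  x$chimera_type_mix <- unlist(x$chimera_type_mix)
  do.call(method_profile, x)
}
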