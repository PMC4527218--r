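#' Pipeline run configuration
#'
#' Bundles every tunable constant of the evaluation pipeline with its
#' standard default: 100 kb depth windows, 10,000 genome bins, 1 Mb minimum
#' CNV length, 100 bp chimera matching threshold, 3e9 assessable genome
#' sites for the FP ratio, GC strata cutoffs 0.50/0.35, and segmentation
#' alpha 0.01. Configurations serialize to YAML and round-trip exactly.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param window_width Depth window width in bp.
#' @param n_bins Number of copy-number bins genome-wide.
#' @param cnv_min_length Minimum CNV span in bp.
#' @param chimera_threshold Breakpoint matching distance in bp.
#' @param genome_sites FP-ratio denominator.
#' @param gc_high,gc_low GC strata cutoffs.
#' @param alpha Segmentation significance level.
#' @param n_sites Golden-control sites for simulation runs.
#' @param mean_count_per_bin Mean diploid bin count for simulation runs.
#' @param profile Name of a [wga_profiles()] preset used by simulation runs.
#' @param paths Named list of input/output file paths.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, window_width = 1e5, n_bins = 10000,
                       cnv_min_length = 1e6, chimera_threshold = 100,
                       genome_sites = 3e9, gc_high = 0.50, gc_low = 0.35,
                       alpha = 0.01, n_sites = 20000,
                       mean_count_per_bin = 600, profile = "mda2",
                       paths = list()) {
  stopifnot(window_width > 0, n_bins >= 1, cnv_min_length >= 0,
            chimera_threshold >= 0, genome_sites > 0,
            gc_low < gc_high, alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), window_width = window_width,
                 n_bins = n_bins, cnv_min_length = cnv_min_length,
                 chimera_threshold = chimera_threshold,
                 genome_sites = genome_sites, gc_high = gc_high,
                 gc_low = gc_low, alpha = alpha, n_sites = n_sites,
                 mean_count_per_bin = mean_count_per_bin, profile = profile,
                 paths = paths),
            class = "run_config")
}

#' @param config A `run_config`.
#' @param path YAML file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  do.call(run_config, yaml::read_yaml(path))
}

default_paths <- function(out_dir) {
  list(control = file.path(out_dir, "golden_control.tsv"),
       calls = file.path(out_dir, "single_cell_calls.tsv"),
       counts_cell = file.path(out_dir, "binned_counts_cell.tsv"),
       counts_control = file.path(out_dir, "binned_counts_control.tsv"),
       cnv_truth = file.path(out_dir, "cnv_truth.tsv"),
       breakpoints_cell = file.path(out_dir, "breakpoints_cell.tsv"),
       breakpoints_control = file.path(out_dir, "breakpoints_control.tsv"),
       depth_track = file.path(out_dir, "depth_track.tsv"))
}

resolve_path <- function(config, out_dir, key) {
  config$paths[[key]] %||% default_paths(out_dir)[[key]]
}

require_input <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  path
}

#' Run an evaluation pipeline stage
#'
#' Executes one stage of the WGA evaluation on the files named in the
#' configuration (or the defaults inside `out_dir`): `"simulate"` writes a
#' full synthetic data set (golden control, single-cell calls, binned
#' counts for cell and unamplified control with shared spiked CNV truth,
#' breakpoint sets, depth track); `"concordance"`, `"uniformity"`, `"cnv"`
#' and `"chimera"` analyse those files and write TSV/JSON summaries;
#' `"report"` renders concordance and SNV summary tables. Identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param subcommand One of `"simulate"`, `"concordance"`, `"uniformity"`,
#'   `"cnv"`, `"chimera"`, `"report"`.
#' @param out_dir Output directory (created if missing).
#' @return A named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "concordance",
                                        "uniformity", "cnv", "chimera",
                                        "report"),
                         out_dir = "scwgaeval_run") {
  stopifnot(inherits(config, "run_config"))
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- wga_profiles()[[config$profile]] %||%
    abort(paste0("Unknown profile preset: ", config$profile))
  genome <- human_like_genome(3e9)
  written <- list()
  p <- function(key) resolve_path(config, out_dir, key)

  if (subcommand == "simulate") {
    control <- simulate_golden_control(genome, config$n_sites,
                                       seed = config$seed)
    calls <- simulate_single_cell_calls(control, prof, seed = config$seed + 1)
    bins <- make_bins(genome, config$n_bins)
    truth <- simulate_cnv_regions(genome, seed = config$seed + 2)
    cell_counts <- simulate_binned_counts(bins, NULL, prof,
                                          config$mean_count_per_bin,
                                          seed = config$seed + 3) |>
      spike_in(truth)
    ctl_counts <- simulate_binned_counts(bins, NULL, wga_profiles()$bulk,
                                         config$mean_count_per_bin,
                                         seed = config$seed + 4) |>
      spike_in(truth)
    true_bp <- simulate_true_breakpoints(genome, n = 200,
                                         seed = config$seed + 5)
    bps <- simulate_breakpoints(true_bp, prof, genome,
                                jitter = config$chimera_threshold / 2,
                                seed = config$seed + 6)
    track <- simulate_depth_track(genome, config$window_width,
                                  dispersion = prof$bin_dispersion,
                                  seed = config$seed + 7)
    written <- list(control = write_genotypes(control, p("control")),
                    calls = write_genotypes(calls, p("calls")),
                    counts_cell = write_intervals(cell_counts, p("counts_cell")),
                    counts_control = write_intervals(ctl_counts,
                                                     p("counts_control")),
                    cnv_truth = write_intervals(truth, p("cnv_truth")),
                    breakpoints_cell = write_breakpoints(bps$cell,
                                                         p("breakpoints_cell")),
                    breakpoints_control =
                      write_breakpoints(bps$control, p("breakpoints_control")),
                    depth_track = write_intervals(track, p("depth_track")))
  } else if (subcommand == "concordance") {
    control <- read_genotypes(require_input(p("control")))
    calls <- read_genotypes(require_input(p("calls")))
    conc <- concordance_matrix(calls, control)
    rates <- estimate_artifact_rates(calls, control)
    out_tsv <- file.path(out_dir, "concordance_table.tsv")
    out_json <- file.path(out_dir, "concordance_metrics.json")
    readr::write_tsv(report_concordance_table(conc), out_tsv)
    jsonlite::write_json(
      c(as.list(glance(conc)), as.list(rates)),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- list(table = out_tsv, metrics = out_json)
  } else if (subcommand == "uniformity") {
    track <- read_intervals(require_input(p("depth_track")))
    nd <- normalized_depth(track)
    nd <- gc_stratify(nd, high = config$gc_high, low = config$gc_low)
    cum <- cumulative_depth_distribution(track$depth, 0:60)
    out_windows <- file.path(out_dir, "normalized_depth.tsv")
    out_cum <- file.path(out_dir, "cumulative_depth.tsv")
    readr::write_tsv(nd, out_windows)
    readr::write_tsv(cum, out_cum)
    written <- list(windows = out_windows, cumulative = out_cum)
  } else if (subcommand == "cnv") {
    cell <- read_intervals(require_input(p("counts_cell")))
    ctl <- read_intervals(require_input(p("counts_control")))
    res_cell <- cnv_pipeline(cell, alpha = config$alpha,
                             min_length = config$cnv_min_length,
                             seed = config$seed)
    res_ctl <- cnv_pipeline(ctl, alpha = config$alpha,
                            min_length = config$cnv_min_length,
                            seed = config$seed)
    ev <- evaluate_cnvs(res_cell$calls, res_ctl$calls,
                        min_length = config$cnv_min_length)
    out_calls <- file.path(out_dir, "cnv_calls.tsv")
    out_eval <- file.path(out_dir, "cnv_evaluation.json")
    readr::write_tsv(res_cell$calls, out_calls)
    jsonlite::write_json(as.list(ev), out_eval, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- list(calls = out_calls, evaluation = out_eval)
  } else if (subcommand == "chimera") {
    cell <- read_breakpoints(require_input(p("breakpoints_cell")))
    ctl <- read_breakpoints(require_input(p("breakpoints_control")))
    labeled <- match_breakpoints(cell, ctl,
                                 max_distance = config$chimera_threshold)
    fr <- chimera_type_fractions(labeled)
    out_lab <- file.path(out_dir, "breakpoints_labeled.tsv")
    out_fr <- file.path(out_dir, "chimera_fractions.tsv")
    readr::write_tsv(labeled, out_lab)
    readr::write_tsv(fr, out_fr)
    written <- list(labeled = out_lab, fractions = out_fr)
  } else if (subcommand == "report") {
    control <- read_genotypes(require_input(p("control")))
    calls <- read_genotypes(require_input(p("calls")))
    conc <- concordance_matrix(calls, control)
    sm <- snv_metrics(calls, control, genome_sites = config$genome_sites)
    out_t2 <- file.path(out_dir, "report_concordance.tsv")
    out_t3 <- file.path(out_dir, "report_snv_metrics.tsv")
    readr::write_tsv(report_concordance_table(conc), out_t2)
    readr::write_tsv(report_snv_table(list(cell = sm)), out_t3)
    written <- list(concordance = out_t2, snv = out_t3)
  }
  invisible(written)
}

#' Render a concordance object as a summary table
#'
#' Wide layout with one row per (single-cell category, share level), one
#' column per control category, plus row totals and per-row consistency,
#' and a final coverage row (detected / control per category).
#'
#' @param conc A `wga_concordance` object.
#' @return A tibble.
#' @export
report_concordance_table <- function(conc) {
  stopifnot(inherits(conc, "wga_concordance"))
  wide <- conc$cells |>
    mutate(share = paste0("share", .data$share)) |>
    tidyr::pivot_wider(names_from = "control_category",
                       values_from = "count", values_fill = 0)
  for (cc in cat_levels) if (is.null(wide[[cc]])) wide[[cc]] <- 0
  cons <- consistency(conc)
  wide <- wide |>
    mutate(total = .data$HOMref + .data$HOMmut + .data$HETref) |>
    arrange(.data$sc_category, dplyr::desc(.data$share))
  cov <- cgde(conc)
  bottom <- tibble(sc_category = factor(NA, cat_levels),
                   share = c("detected", "control", "coverage_pct"),
                   HOMref = c(conc$detected_totals[1], conc$control_totals[1],
                              100 * cov$cgde[1]),
                   HOMmut = c(conc$detected_totals[2], conc$control_totals[2],
                              100 * cov$cgde[2]),
                   HETref = c(conc$detected_totals[3], conc$control_totals[3],
                              100 * cov$cgde[3]),
                   total = c(sum(conc$detected_totals),
                             sum(conc$control_totals),
                             100 * cov$cgde[4]))
  wide$consistency_pct <- 100 *
    cons$consistency[match(as.character(wide$sc_category), cons$category)] *
    ifelse(wide$share == "share2", 1, NA)
  bottom$consistency_pct <- c(100 * cons$consistency[cons$category == "overall"],
                              NA, NA)
  bind_rows(wide, bottom)
}

#' Render SNV metrics for one or more cells as a summary table
#'
#' @param metrics Named list of `wga_snv_metrics` objects.
#' @return A tibble with one row per cell: detected/FP/ADO counts per
#'   zygosity, efficiencies, FP ratio and ADO ratio.
#' @export
report_snv_table <- function(metrics) {
  purrr::imap_dfr(metrics, function(m, nm) {
    tibble(sample = nm,
           detected_het = m$detected_het, fp_het = m$fp_het,
           ado_count = m$ado_count,
           detected_hom = m$detected_hom, fp_hom = m$fp_hom,
           detected_total = m$detected_total, fp_total = m$fp_total,
           efficiency_gross = m$efficiency_gross,
           efficiency_net = m$efficiency_net,
           fp_ratio = m$fp_ratio, ado_ratio = m$ado_ratio)
  })
}
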