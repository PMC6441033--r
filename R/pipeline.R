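#' Default study generator configuration
#'
#' Builds the control-condition generative model the comparative pipeline
#' is exercised on: a 20-kb-binned cis map with power-law decay `s^-1`,
#' TAD blocks of 10-35 bins (intra boosts 2-4) tiling the chromosome with
#' occasional gaps, loop dots inside larger TADs, a smooth compartment
#' checkerboard, and log-normal per-bin biases.
#'
#' @param seed master seed.
#' @param n_bins number of bins (default 500, i.e. a 10-Mb chromosome).
#' @param resolution bin width (default 20 kb).
#' @param depth expected total read pairs (default 5e6).
#' @return A [simulation_config].
#' @export
study_simulation_config <- function(seed = 1L, n_bins = 500L,
                                    resolution = 20000L, depth = 5e6) {
  layout <- with_seed(sub_seed(seed, "layout"), {
    tads <- NULL
    pos <- 0L
    while (pos < n_bins - 12L) {
      size <- sample(10:35, 1)
      if (pos + size > n_bins) size <- n_bins - pos
      if (size >= 5L)
        tads <- rbind(tads, data.frame(start_bin = pos, end_bin = pos + size,
                                       intra_boost = stats::runif(1, 2, 4)))
      pos <- pos + size + sample(c(0L, 0L, 0L, 2L), 1)  # occasional gaps
    }
    loops <- NULL
    for (t in seq_len(nrow(tads))) {
      if (tads$end_bin[t] - tads$start_bin[t] >= 15L && stats::runif(1) < 0.6) {
        loops <- rbind(loops, data.frame(bin_i = tads$start_bin[t] + 1L,
                                         bin_j = tads$end_bin[t] - 2L,
                                         loop_boost = 6))
      }
    }
    comp <- 0.9 * sin(2 * pi * seq_len(n_bins) / 80 +
                        stats::runif(1, 0, 2 * pi))
    bias <- stats::rlnorm(n_bins, 0, 0.2)
    list(tads = tads, loops = loops, comp = comp, bias = bias)
  })
  simulation_config(seed = seed, n_bins = n_bins, resolution = resolution,
                    decay_exponent = -1.0,
                    tad_spec = layout$tads, loop_spec = layout$loops,
                    compartment_profile = layout$comp,
                    compartment_strength = 0.6,
                    bias_vector = layout$bias, depth = depth)
}

#' Validate a pipeline run configuration
#'
#' Checks a configuration list (or YAML file) against the pipeline's
#' invariants, aggregating all violations into one error. Unknown keys
#' produce a warning, never silent defaults for required fields.
#'
#' @param config a named list or a YAML file path.
#' @return A validated `run_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(resolution = 20000L, n_bins = 500L, depth = 5e6,
                   gamma = 0.3, fdr = 0.05, peak_threshold = 0.5,
                   desert_min_length = 500000L, min_contact_sep = 40000L,
                   seed = 1L, output_dir = NULL, fret = TRUE)
  known <- names(defaults)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[intersect(names(config), known)])
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$resolution) && cfg$resolution > 0,
      "resolution must be positive")
  chk(is.numeric(cfg$n_bins) && cfg$n_bins >= 50, "n_bins must be >= 50")
  chk(is.numeric(cfg$depth) && cfg$depth > 0, "depth must be positive")
  chk(is.numeric(cfg$gamma) && cfg$gamma >= 0, "gamma must be >= 0")
  chk(is.numeric(cfg$fdr) && cfg$fdr > 0 && cfg$fdr < 1,
      "fdr must be in (0, 1)")
  chk(is.numeric(cfg$peak_threshold) && cfg$peak_threshold > 0 &&
        cfg$peak_threshold < 1, "peak_threshold must be in (0, 1)")
  chk(is.numeric(cfg$desert_min_length) && cfg$desert_min_length > 0,
      "desert_min_length must be positive")
  chk(is.numeric(cfg$min_contact_sep) && cfg$min_contact_sep > 0,
      "min_contact_sep must be positive")
  chk(is.numeric(cfg$seed), "seed must be an integer")
  if (length(errs)) stop("invalid config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full control-vs-treated comparison pipeline
#'
#' Simulates paired conditions from the study generator, then executes the
#' comparison stages in order: depth normalization, iterative correction,
#' observed/expected, control TAD segmentation, paired border-strength
#' comparison, compartment profiles and saddles (control eigenvector
#' ordering for both conditions), scaling curves with crossover, contact
#' calls with persistence classification, peak persistence, gene-desert
#' analyses, and (optionally) spFRET mixture fits. Deterministic under the
#' master seed.
#'
#' @param config a `run_config` (see [validate_config()]) or a list/path
#'   accepted by it.
#' @return A `comparison_report` list with one section per stage, each
#'   recording the parameters that produced it.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  sim <- study_simulation_config(seed = config$seed, n_bins = config$n_bins,
                                 resolution = config$resolution,
                                 depth = config$depth)
  pert <- perturbation_preset("treated")
  ctrl <- simulate_contact_map(sim)
  trt <- simulate_contact_map(sim, pert)

  bal_c <- iterative_correction(ctrl$map)
  bal_t <- iterative_correction(trt$map)
  oe_c <- observed_over_expected(bal_c)
  oe_t <- observed_over_expected(bal_t)
  norm_c <- normalize_depth(ctrl$map)
  norm_t <- normalize_depth(trt$map)

  seg_c <- armatus_segment(bal_c, gamma = config$gamma)
  seg_t <- armatus_segment(bal_t, gamma = config$gamma)
  borders <- compare_borders(bal_c, bal_t, seg_c)

  prof_c <- compartment_profile(oe_c, sim$gc_track)
  prof_t <- compartment_profile(oe_t, sim$gc_track)
  sad_c <- saddle(oe_c, prof_c)
  sad_t <- saddle(oe_t, prof_c)  # control eigenvector ordering, both maps
  comp <- list(
    strength_control = compartmentalization_strength(sad_c),
    strength_treated = compartmentalization_strength(sad_t),
    fractions_control = compartment_contact_fractions(norm_c, prof_c),
    fractions_treated = compartment_contact_fractions(norm_t, prof_t))

  curve_c <- contact_probability_curve(norm_c)
  curve_t <- contact_probability_curve(norm_t)
  scaling <- list(
    slope_control = scaling_slope(curve_c, 1e5, 2e6),
    slope_treated = scaling_slope(curve_t, 1e5, 2e6),
    crossover = crossover_report(curve_c, curve_t))

  calls_c <- call_contacts(bal_c, seg_c, fdr = config$fdr,
                           min_sep = config$min_contact_sep)
  calls_t <- call_contacts(bal_t, seg_c, fdr = config$fdr,
                           min_sep = config$min_contact_sep)
  persistence <- classify_persistence(calls_c, calls_t)

  peaks <- simulate_peak_sets(sim, pert)
  peak_report <- classify_peaks(peaks$control, peaks$treated,
                                threshold = config$peak_threshold)

  anno <- simulate_genome_annotation(sim)
  deserts <- annotate_deserts(anno$genes, config$n_bins * config$resolution,
                              min_length = config$desert_min_length)
  rna <- bin_rna_signal(anno$rna, bin_size = config$resolution)
  desert_section <- list(
    deserts = deserts,
    rna = rna_signal_summary(rna, deserts),
    borders = desert_border_comparison(bal_t, seg_t, deserts))

  fret_section <- NULL
  if (isTRUE(config$fret)) {
    fit1 <- fit_gaussian_mixture(build_distribution(
      simulate_fret_events(fret_preset("minus_drug"), 2832L,
                           sub_seed(config$seed, "fret_minus"))), 2L)
    fit2 <- fit_gaussian_mixture(build_distribution(
      simulate_fret_events(fret_preset("plus_drug"), 4310L,
                           sub_seed(config$seed, "fret_plus"))), 2L)
    fret_section <- list(fit_minus = fit1, fit_plus = fit2,
                         deltas = compare_conditions(fit1, fit2))
  }

  report <- list(
    config = unclass(config),
    tads = list(control = seg_c, treated = seg_t),
    borders = borders,
    compartments = comp,
    scaling = scaling,
    contacts = list(n_control = nrow(calls_c), n_treated = nrow(calls_t),
                    persistence = persistence),
    peaks = peak_report,
    deserts = desert_section,
    fret = fret_section)
  class(report) <- "comparison_report"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Flatten a comparison report to plain summary numbers
#'
#' @param report a [run_pipeline()] result.
#' @return A nested list of plain numbers suitable for JSON export.
#' @export
report_summary <- function(report) {
  b <- report$borders
  list(
    seed = report$config$seed,
    n_bins = report$config$n_bins,
    borders = list(
      n = b$summary$n_borders,
      median_control = unname(b$summary$control[2]),
      median_treated = unname(b$summary$treated[2]),
      fraction_below_diagonal = b$summary$fraction_below_diagonal,
      p_value = if (!is.null(b$test)) b$test$p.value else NULL),
    compartments = list(
      strength_control = report$compartments$strength_control,
      strength_treated = report$compartments$strength_treated,
      ab_fraction_control = unname(report$compartments$fractions_control["AB"]),
      ab_fraction_treated = unname(report$compartments$fractions_treated["AB"])),
    scaling = list(
      slope_control = report$scaling$slope_control,
      slope_treated = report$scaling$slope_treated,
      crossover_bp = report$scaling$crossover),
    contacts = as.list(report$contacts$persistence$fractions),
    peaks = list(n_control = report$peaks$n_control,
                 n_remaining = report$peaks$n_remaining,
                 n_lost = report$peaks$n_lost,
                 n_novel = report$peaks$n_novel),
    desert_border_p = if (!is.null(report$deserts$borders$test))
      report$deserts$borders$test$p.value else NULL,
    fret = if (!is.null(report$fret)) list(
      closed_fraction_minus = report$fret$fit_minus$components$area_fraction[2],
      open_fraction_plus = report$fret$fit_plus$components$area_fraction[1],
      closed_mean_minus = report$fret$fit_minus$components$mean[2],
      closed_mean_plus = report$fret$fit_plus$components$mean[2]) else NULL)
}
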