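#' Configuration for an end-to-end analysis run
#'
#' Exactly one data source must be given: a census CSV (`census_path`) or a
#' simulation configuration (`sim`).
#'
#' @param census_path Path to a census file for [read_census()].
#' @param sim A [sim_config()] for [generate_experiment()].
#' @param window,light_map Used when reading a census without a sidecar.
#' @param subplot_grid `c(ncols, nrows)` for the subplot-level analysis.
#' @param r_grid,bandwidth,correction,band_type Passed to
#'   [delta_pcf_summary()].
#' @param var_equal Pooled-variance two-sample t (default) or Welch.
#' @param permutation Also run the block-restricted permutation test?
#' @param n_perm Permutations for it.
#' @param seed Root seed for analysis-stage randomness (permutation).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(census_path = NULL, sim = NULL,
                            window = c(width = 1.1, height = 0.9),
                            light_map = default_light_map(),
                            subplot_grid = c(3, 2),
                            r_grid = NULL, bandwidth = NULL,
                            correction = "isotropic",
                            band_type = "t_ci_95",
                            var_equal = TRUE,
                            permutation = FALSE, n_perm = 999,
                            seed = 1L) {
  if (is.null(census_path) == is.null(sim)) {
    abort("give exactly one of `census_path` or `sim`",
          class = "grass_argument_error")
  }
  structure(list(census_path = census_path, sim = sim, window = window,
                 light_map = light_map, subplot_grid = subplot_grid,
                 r_grid = r_grid, bandwidth = bandwidth,
                 correction = correction, band_type = band_type,
                 var_equal = var_equal, permutation = permutation,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Acquires the experiment (read or simulate), runs the plot- and
#' subplot-level delta-B analysis with its t tests and the illumination
#' regression, the per-treatment delta-pcf bands with interaction calls,
#' and the per-treatment diversity-change summary. Identical configs and
#' seeds give identical reports.
#'
#' @param config An [analysis_config()].
#' @return A `grass_report`: list with `experiment`, `pairs_plots`,
#'   `pairs_subplots`, `tests`, `regression`, `regression_band`,
#'   `delta_pcf`, `diversity`, optional `permutation`, and `manifest`.
#' @export
run_analysis <- function(config) {
  experiment <- if (!is.null(config$census_path)) {
    read_census(config$census_path, window = config$window,
                light_map = config$light_map)
  } else {
    generate_experiment(config$sim)
  }

  pairs_plots <- delta_dissimilarity(experiment, level = "plots")
  pairs_subplots <- delta_dissimilarity(
    experiment, level = "subplots",
    ncols = config$subplot_grid[1], nrows = config$subplot_grid[2]
  )
  tests <- delta_b_tests(bind_rows(pairs_plots, pairs_subplots),
                         var_equal = config$var_equal)
  # the regression needs >= 3 between-treatment pairs spanning >= 2 light
  # contrasts; on tiny inputs it is reported as absent rather than failing
  regression <- tryCatch(regress_delta_on_light(pairs_plots),
                         error = function(e) NULL)
  pcf_summary <- delta_pcf_summary(
    experiment, r_grid = config$r_grid, bandwidth = config$bandwidth,
    correction = config$correction, band_type = config$band_type
  )
  diversity <- diversity_change_summary(experiment)

  permutation <- NULL
  if (config$permutation) {
    permutation <- delta_b_permutation(pairs_plots, n_perm = config$n_perm,
                                       seed = stage_seed(config$seed, 9))
  }

  manifest <- list(
    package = "shadegrass",
    package_version = as.character(utils::packageVersion("shadegrass")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    source = if (is.null(config$census_path)) "simulated" else
      config$census_path,
    sim = if (is.null(config$sim)) NULL else unclass(config$sim),
    subplot_grid = config$subplot_grid,
    band_type = config$band_type,
    correction = config$correction,
    pcf_bandwidth = attr(pcf_summary, "bandwidth", exact = TRUE),
    n_plots = length(unique(experiment$plot_id)),
    n_individuals_t1 = sum(experiment$census == "t1"),
    n_individuals_t2 = sum(experiment$census == "t2"),
    n_dropped_pairs_plots = attr(pairs_plots, "n_dropped", exact = TRUE),
    n_dropped_pairs_subplots = attr(pairs_subplots, "n_dropped", exact = TRUE)
  )

  structure(list(
    experiment = experiment,
    pairs_plots = pairs_plots,
    pairs_subplots = pairs_subplots,
    tests = tests,
    regression = regression,
    regression_band = if (!is.null(regression)) confidence_band(regression),
    delta_pcf = pcf_summary,
    diversity = diversity,
    permutation = permutation,
    manifest = manifest
  ), class = "grass_report")
}

#' @export
print.grass_report <- function(x, ...) {
  cat("<grass_report>\n")
  cat(sprintf("  %d plots, %d + %d individuals (t1 + t2)\n",
              x$manifest$n_plots, x$manifest$n_individuals_t1,
              x$manifest$n_individuals_t2))
  cat("  delta-B tests:\n")
  print(x$tests)
  if (!is.null(x$regression)) print(x$regression)
  calls <- count(x$delta_pcf, .data$treatment, .data$classification)
  cat("  interaction calls (r-grid points per treatment):\n")
  print(calls)
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Plain CSV tables plus one JSON manifest, so results diff cleanly.
#'
#' @param report A `grass_report` from [run_analysis()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_csv(report$pairs_plots, p("pair_dissimilarity.csv"))
  readr::write_csv(report$pairs_subplots, p("pair_dissimilarity_subplots.csv"))
  readr::write_csv(report$tests, p("dissimilarity_tests.csv"))
  if (!is.null(report$regression)) {
    readr::write_csv(tidy(report$regression), p("light_regression.csv"))
  }
  readr::write_csv(report$delta_pcf, p("delta_pcf.csv"))
  readr::write_csv(
    select(report$delta_pcf, "treatment", "r", "classification"),
    p("interaction_calls.csv")
  )
  readr::write_csv(report$diversity$plots, p("diversity_plots.csv"))
  readr::write_csv(report$diversity$treatments, p("diversity_treatments.csv"))
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
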