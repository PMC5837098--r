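#' Experiment configuration
#'
#' A `run_config` captures everything needed to reproduce an experiment:
#' the experiment name, its parameters, the replicate count, connectivity,
#' seed and output directory. Configs serialize to YAML and round-trip
#' exactly, so a run can be reproduced from its saved file.
#'
#' @param experiment one of `"spot-sweep"`, `"compare-methods"`,
#'   `"table1"`, `"table2"`, `"fit"`, `"render-grid"`.
#' @param params named list of experiment parameters (see
#'   [run_from_config()] for the recognized fields of each experiment).
#' @param n_replicates replicates per cell/rate.
#' @param connectivity 4 or 8 (spot labeling).
#' @param seed integer RNG seed.
#' @param output_dir directory for result files.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(experiment, params = list(), n_replicates = NULL,
                       connectivity = 8, seed = 1, output_dir = ".") {
  experiment <- match.arg(experiment,
                          c("spot-sweep", "compare-methods", "table1",
                            "table2", "fit", "render-grid"))
  if (is.null(n_replicates))
    n_replicates <- if (experiment == "spot-sweep") 1000 else 200
  structure(list(experiment = experiment, params = params,
                 n_replicates = as.integer(n_replicates),
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(experiment = x$experiment, params = x$params,
             n_replicates = x$n_replicates, connectivity = x$connectivity,
             seed = x$seed, output_dir = x$output_dir)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %s (seed %d, %d replicates, output '%s')\n",
              x$experiment, x$seed, x$n_replicates, x$output_dir))
  invisible(x)
}

#' Execute an experiment from a configuration
#'
#' Dispatches on `config$experiment`, writes the result files into
#' `config$output_dir` and a `manifest.json` recording the config, seed,
#' package version, wall time and output names. On error, partial outputs
#' of this run are removed.
#'
#' Experiments and their `params` fields (all optional, with the package
#' defaults):
#' \describe{
#'   \item{`spot-sweep`}{`rates`, `n_rows`, `n_cols`, `row_spacing` —
#'     writes `spot_sweep.csv` with the five summary columns.}
#'   \item{`compare-methods`}{`optimum_densities`, `max_yields`,
#'     `sensitivities`, `rates`, `row_spacing`, `field_width`,
#'     `field_height` — writes the long-format `method_comparison.csv`.}
#'   \item{`table1`}{as `compare-methods` plus `sensitivity` (default
#'     112) — writes `yield_reduction_regression.csv`.}
#'   \item{`table2`}{as `compare-methods` — writes
#'     `sensitivity_rate_regression.csv`.}
#'   \item{`fit`}{`input` (a spot-sweep CSV; default the published
#'     reference table) — writes `spot_fits.json` with the quadratic
#'     (hundred-dot spots) and exponential (spot missing seedlings)
#'     fits.}
#'   \item{`render-grid`}{`density`, `rate`, `row_spacing`,
#'     `field_width`, `field_height`, `format` (png/pgm) — writes a
#'     binary grid image.}
#' }
#'
#' @param config a [run_config()] (or path to a YAML config file).
#' @return Invisibly, the character vector of files written.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  gp <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  t0 <- Sys.time()
  files <- character(0)
  out <- function(name) {
    files <<- c(files, file.path(config$output_dir, name))
    files[length(files)]
  }
  res <- tryCatch({
    switch(config$experiment,
      "spot-sweep" = {
        lay <- field_layout(gp("n_rows", 60), gp("n_cols", 120),
                            gp("row_spacing", 0.6),
                            gp("row_spacing", 0.6) / 2)
        sw <- spot_rate_sweep(lay,
                              rates = gp("rates",
                                         c(0.95, 0.925, 0.9, 0.85, 0.8,
                                           0.75, 0.7)),
                              n_replicates = config$n_replicates,
                              connectivity = config$connectivity,
                              seed = config$seed)
        cols <- c("rate", "mean_missing", "mean_spots", "hundred_dot_spot",
                  "spot_missing_seedling")
        write.csv(as.data.frame(sw)[, cols], out("spot_sweep.csv"),
                  row.names = FALSE)
      },
      "compare-methods" = ,
      "table1" = ,
      "table2" = {
        cmp <- run_method_comparison(
          optimum_densities = gp("optimum_densities",
                                 c(4.5, 6, 7.5, 9, 10.5, 12)),
          max_yields = gp("max_yields", c(5.25, 7.5, 9.75, 12, 14.25)),
          sensitivities = gp("sensitivities", c(16, 48, 80, 112)),
          rates = gp("rates", c(0.75, 0.85, 0.9, 0.95)),
          n_replicates = config$n_replicates,
          row_spacing = gp("row_spacing", 0.6),
          field_width = gp("field_width", 36),
          field_height = gp("field_height", 36),
          seed = config$seed)
        write.csv(as.data.frame(cmp), out("method_comparison.csv"),
                  row.names = FALSE)
        if (config$experiment == "table1")
          write.csv(yield_reduction_regression(cmp,
                                               gp("sensitivity", 112)),
                    out("yield_reduction_regression.csv"),
                    row.names = FALSE)
        if (config$experiment == "table2")
          write.csv(sensitivity_rate_regression(cmp),
                    out("sensitivity_rate_regression.csv"),
                    row.names = FALSE)
      },
      "fit" = {
        tab <- if (is.null(p$input)) reference_spot_table() else
          read.csv(p$input)
        fq <- fit_quadratic(tab$rate, tab$hundred_dot_spot)
        fe <- fit_exponential(tab$rate, tab$spot_missing_seedling)
        jsonlite::write_json(
          list(hundred_dot_spot = .fit_as_list(fq),
               spot_missing_seedling = .fit_as_list(fe)),
          out("spot_fits.json"), auto_unbox = TRUE, digits = NA)
      },
      "render-grid" = {
        lay <- layout_from_density(gp("density", 60000),
                                   gp("row_spacing", 0.6),
                                   gp("field_width", 36),
                                   gp("field_height", 36))
        g <- simulate_emergence(lay, gp("rate", 0.85), seed = config$seed)
        export_grid_image(g, out(paste0("grid.", gp("format", "png"))))
      })
    TRUE
  }, error = function(e) {
    unlink(files)
    stop("experiment '", config$experiment, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package = "sowsim",
    version = as.character(packageVersion("sowsim")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = basename(files))
  mf <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

.fit_as_list <- function(fit) {
  list(model_kind = fit$model_kind,
       coefficients = as.list(fit$coefficients),
       r_squared = fit$r_squared,
       vertex = if (!is.null(fit$vertex)) as.list(fit$vertex),
       x_range = fit$x_range, y_range = fit$y_range)
}
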