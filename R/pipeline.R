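# Pipeline layer: each fis_* function is one stage of the
# simulate -> induce -> predict -> validate workflow, writing its results
# under an output directory and returning them invisibly. The thin
# command-line dispatcher at inst/cli/ribofis.R calls straight into these.

pipeline_msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Simulate OFAT experiments and write one CSV per factor
#'
#' @param config A [simulation_config()]; default
#'   [default_simulation_config()] with `seed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed used when `config` is not supplied.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the datasets and the file paths written.
#' @export
fis_simulate <- function(config = NULL, out_dir, seed = 1L, quiet = FALSE) {
  if (is.null(config)) config <- default_simulation_config(seed)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- generate_ofat(config)
  paths <- vapply(names(datasets), function(f) {
    p <- file.path(out_dir, sprintf("ofat_%s.csv", f))
    write_ofat_csv(datasets[[f]], p)
    p
  }, character(1))
  pipeline_msg(quiet, "simulated %d OFAT dataset(s) (seed %d): %s",
               length(datasets), config$seed,
               paste(sprintf("%s (%d obs)", names(datasets),
                             vapply(datasets, function(d) nrow(d$observations),
                                    integer(1))),
                     collapse = ", "))
  invisible(list(datasets = datasets, paths = paths, config = config))
}

#' Induce rule bases and fuzzy models from OFAT CSV files
#'
#' Reads the given CSV files (or every `ofat_*.csv` in a directory),
#' induces one rule base per factor, builds the four single-factor
#' Mamdani models and writes them as JSON next to a combined provenance
#' report.
#'
#' @param input Character vector of CSV paths, or a directory containing
#'   `ofat_*.csv` files.
#' @param out_dir Output directory for `model_<factor>.json` files and
#'   `provenance.csv`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `rulebases`, `models` and `paths`.
#' @export
fis_induce <- function(input, out_dir, quiet = FALSE) {
  if (length(input) == 1L && dir.exists(input)) {
    input <- list.files(input, pattern = "^ofat_.*\\.csv$", full.names = TRUE)
  }
  if (length(input) == 0L) stop("no OFAT CSV files to read", call. = FALSE)
  datasets <- list()
  for (p in input) datasets <- c(datasets, read_ofat_csv(p))
  rulebases <- induce_all(datasets)
  models <- lapply(riboflavin_factors(), function(f) {
    build_single_factor_model(f, rulebases[[f]])
  })
  names(models) <- riboflavin_factors()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(riboflavin_factors(), function(f) {
    p <- file.path(out_dir, sprintf("model_%s.json", f))
    write_fis_json(models[[f]], p)
    p
  }, character(1))
  prov_path <- file.path(out_dir, "provenance.csv")
  write_provenance_csv(rulebases, prov_path)
  pipeline_msg(quiet, "induced %s rule(s) for factors %s",
               paste(vapply(rulebases, function(rb) length(rb$rules),
                            integer(1)), collapse = "/"),
               paste(riboflavin_factors(), collapse = "/"))
  invisible(list(rulebases = rulebases, models = models,
                 paths = c(paths, provenance = prov_path)))
}

#' Predict riboflavin from a serialized single-factor model
#'
#' @param model A `mamdani_model` or the path of a JSON model file.
#' @param level Dose(s) (g/L) to predict at; mutually exclusive with `grid`.
#' @param grid If given, number of equally spaced doses spanning the
#'   input universe to predict over.
#' @return Data frame with columns `level` and `predicted` (ug/L).
#' @export
fis_predict <- function(model, level = NULL, grid = NULL) {
  if (is.character(model)) model <- read_fis_json(model)
  stopifnot(inherits(model, "mamdani_model"))
  if (length(model$inputs) != 1L) {
    stop("fis_predict expects a single-factor model; use predict() for joint models",
         call. = FALSE)
  }
  if (is.null(level) == is.null(grid)) {
    stop("supply exactly one of 'level' or 'grid'", call. = FALSE)
  }
  var <- model$inputs[[1]]
  if (!is.null(grid)) {
    level <- seq(var$universe[1], var$universe[2], length.out = as.integer(grid))
  }
  newdata <- stats::setNames(data.frame(level), var$name)
  data.frame(level = level, predicted = predict(model, newdata))
}

#' Validate predictions against experimental values
#'
#' Builds a [validation_report()] either from the bundled reference
#' interior-point validation pairs or from a CSV with columns `factor`,
#' `level`, `predicted`, `experimental`.
#'
#' @param pairs `"reference"` (default: the four bundled validation rows)
#'   or the path of a pairs CSV.
#' @param out_dir If given, the report is written to
#'   `<out_dir>/validation_report.csv`.
#' @param quiet Suppress progress messages.
#' @return The `validation_report`, invisibly.
#' @export
fis_validate <- function(pairs = "reference", out_dir = NULL, quiet = FALSE) {
  records <- if (identical(pairs, "reference")) {
    fx <- riboflavin_reference()
    df <- fx$pairs[fx$pairs$set == "validation", ]
    df[c("factor", "level", "predicted", "experimental")]
  } else {
    df <- utils::read.csv(pairs, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop(sprintf("'%s' contains no pairs", pairs), call. = FALSE)
    df
  }
  report <- validation_report(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_validation_csv(report, file.path(out_dir, "validation_report.csv"))
  }
  if (!quiet) print(report)
  invisible(report)
}

#' Run the whole pipeline from one configuration
#'
#' simulate -> induce -> predict (21-point dose grids per factor) ->
#' validate (bundled reference pairs), writing everything under `out_dir`.
#'
#' @inheritParams fis_simulate
#' @return Invisibly, a list with the stage results.
#' @export
fis_run_all <- function(config = NULL, out_dir, seed = 1L, quiet = FALSE) {
  sim <- fis_simulate(config, out_dir, seed = seed, quiet = quiet)
  ind <- fis_induce(unname(sim$paths), out_dir, quiet = quiet)
  preds <- lapply(riboflavin_factors(), function(f) {
    df <- fis_predict(ind$models[[f]], grid = 21L)
    utils::write.csv(df, file.path(out_dir, sprintf("predictions_%s.csv", f)),
                     row.names = FALSE, quote = FALSE)
    df
  })
  names(preds) <- riboflavin_factors()
  report <- fis_validate("reference", out_dir, quiet = quiet)
  invisible(list(simulation = sim, induction = ind, predictions = preds,
                 validation = report))
}
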