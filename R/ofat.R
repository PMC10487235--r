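#' One-factor-at-a-time dose-response dataset
#'
#' Observations of riboflavin production while a single medium component is
#' varied and the other factors are held at fixed baseline levels.
#' Replicates are stored long-form, one row per measurement.
#'
#' @param factor Name of the varied factor.
#' @param observations Data frame with numeric columns `level` (g/L),
#'   `response` (ug/L, strictly positive) and integer `replicate`
#'   (defaults to 1 if absent). At least two distinct levels are required.
#' @param baseline Named numeric vector of the held-fixed levels of the
#'   other factors; default [baseline_levels()] minus `factor` when the
#'   factor belongs to the riboflavin catalog, otherwise empty.
#' @return An object of class `ofat_dataset`.
#' @export
ofat_dataset <- function(factor, observations, baseline = NULL) {
  stopifnot(is.character(factor), length(factor) == 1L, nzchar(factor),
            is.data.frame(observations))
  obs <- as.data.frame(observations)
  if (is.null(obs$replicate)) obs$replicate <- 1L
  required <- c("level", "response", "replicate")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0L) {
    stop(sprintf("observations lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  obs <- obs[required]
  if (nrow(obs) == 0L) stop("no observations", call. = FALSE)
  if (!is.numeric(obs$level) || !is.numeric(obs$response)) {
    stop("level and response must be numeric", call. = FALSE)
  }
  if (any(!is.finite(obs$level)) || any(!is.finite(obs$response))) {
    stop("non-finite level or response", call. = FALSE)
  }
  if (any(obs$response <= 0)) {
    stop(sprintf("non-positive response in row %d", which(obs$response <= 0)[1]),
         call. = FALSE)
  }
  obs$replicate <- as.integer(obs$replicate)
  if (any(is.na(obs$replicate)) || any(obs$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (length(unique(obs$level)) < 2L) {
    stop(sprintf("dataset for factor '%s' needs at least 2 distinct levels", factor),
         call. = FALSE)
  }
  if (is.null(baseline)) {
    base <- baseline_levels()
    baseline <- if (factor %in% names(base)) base[setdiff(names(base), factor)]
                else numeric(0)
  }
  rownames(obs) <- NULL
  structure(list(factor = factor, baseline = baseline, observations = obs),
            class = "ofat_dataset")
}

#' @export
print.ofat_dataset <- function(x, ...) {
  cat(sprintf("OFAT dataset: factor '%s', %d observations at %d levels\n",
              x$factor, nrow(x$observations), length(unique(x$observations$level))))
  if (length(x$baseline) > 0) {
    cat("  baseline:", paste(names(x$baseline), x$baseline, sep = " = ",
                             collapse = ", "), "\n")
  }
  print(x$observations)
  invisible(x)
}

#' Read OFAT datasets from CSV
#'
#' Expects a UTF-8 CSV with header columns `factor`, `level`, `response`
#' and optionally `replicate` (default 1). Rows are grouped by factor into
#' one [ofat_dataset()] each; parse and validation failures name the
#' offending data row.
#'
#' @param path CSV file path.
#' @param ranges Optional named list of `c(min, max)` per factor; when
#'   supplied, a level outside its factor's range is an error.
#' @return Named list of `ofat_dataset`s, one per factor, in order of first
#'   appearance.
#' @export
read_ofat_csv <- function(path, ranges = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop(sprintf("'%s' contains no data rows", path), call. = FALSE)
  }
  missing_cols <- setdiff(c("factor", "level", "response"), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$replicate)) df$replicate <- 1L
  for (col in c("level", "response", "replicate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric '%s' value in data row %d of '%s'",
                   col, bad[1], path), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(df$response <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive response in data row %d of '%s'", bad[1], path),
         call. = FALSE)
  }
  if (!is.null(ranges)) {
    for (i in seq_len(nrow(df))) {
      rng <- ranges[[df$factor[i]]]
      if (!is.null(rng) && (df$level[i] < rng[1] || df$level[i] > rng[2])) {
        stop(sprintf(
          "data row %d of '%s': level %g of factor '%s' outside declared range [%g, %g]",
          i, path, df$level[i], df$factor[i], rng[1], rng[2]), call. = FALSE)
      }
    }
  }
  factors <- unique(df$factor)
  datasets <- lapply(factors, function(f) {
    ofat_dataset(f, df[df$factor == f, c("level", "response", "replicate")])
  })
  names(datasets) <- factors
  datasets
}

#' Write OFAT datasets to CSV
#'
#' Inverse of [read_ofat_csv()]; the round trip is lossless (factor, level,
#' response, replicate are preserved; baselines are reconstructed from the
#' catalog on read).
#'
#' @param datasets A single `ofat_dataset` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ofat_csv <- function(datasets, path) {
  if (inherits(datasets, "ofat_dataset")) datasets <- list(datasets)
  stopifnot(is.list(datasets))
  if (length(datasets) == 0L) stop("no datasets to write", call. = FALSE)
  rows <- lapply(datasets, function(d) {
    stopifnot(inherits(d, "ofat_dataset"))
    cbind(data.frame(factor = d$factor, stringsAsFactors = FALSE),
          d$observations)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference experimental/predicted riboflavin values
#'
#' The published interior-point validation fermentations and dose-response
#' checkpoints for riboflavin production by *Lactiplantibacillus plantarum*
#' that this package's validation arithmetic reproduces: for each factor,
#' the concentration tested, the experimentally measured riboflavin and the
#' value the original fuzzy model predicted. `set == "validation"` marks
#' the four interior-point validation rows (factors at 11, 0.03, 12 and
#' 12 g/L); `set == "curve"` marks two dose-response checkpoints at low
#' casamino (5 g/L) and mid GTP (0.02 g/L). Also carries the unoptimized
#' baseline production (346 ug/L) and the optimized production (429 ug/L).
#'
#' @return List with elements `pairs` (data frame: `factor`, `level`,
#'   `experimental`, `predicted`, `set`), `baseline_production` and
#'   `optimized_production` (ug/L).
#' @examples
#' fx <- riboflavin_reference()
#' percent_variation(fx$pairs$experimental, fx$pairs$predicted)
#' @export
riboflavin_reference <- function() {
  path <- system.file("extdata", "riboflavin_validation_reference.csv",
                      package = "ribofis", mustWork = TRUE)
  pairs <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(pairs = pairs,
       baseline_production = 346,
       optimized_production = 429)
}
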