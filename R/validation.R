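# Validation arithmetic: percent variation between experimental and
# predicted riboflavin, headline percent increase, RMSE and Pearson
# correlation, and the aggregated validation report.

# round half away from zero ("half-up" on magnitudes); base round() is
# banker's rounding and would turn e.g. 0.125 into 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent variation between experimental and predicted values
#'
#' `(experimental - predicted) / experimental * 100`, rounded half-up to
#' two decimals. This is the convention under which all four published
#' interior-point validation rows (0.75, 0.29, 0.82, -0.61) are reproduced
#' from their experimental/predicted pairs. Vectorized with recycling.
#'
#' @param experimental Measured riboflavin (ug/L), strictly positive.
#' @param predicted Model-predicted riboflavin (ug/L).
#' @return Signed percentage(s), 2 decimals.
#' @examples
#' percent_variation(386.915, 384)  # 0.75
#' percent_variation(380.69, 383)   # -0.61
#' @export
percent_variation <- function(experimental, predicted) {
  stopifnot(is.numeric(experimental), is.numeric(predicted))
  if (any(experimental <= 0)) {
    stop("experimental value must be > 0", call. = FALSE)
  }
  round_half_up((experimental - predicted) / experimental * 100, 2)
}

#' Percent increase from baseline to optimized production
#'
#' `(optimized - baseline) / baseline * 100`, rounded half-up to an
#' integer — the headline improvement statistic (346 -> 429 ug/L gives 24).
#'
#' @param baseline Unoptimized production (ug/L), > 0.
#' @param optimized Optimized production (ug/L).
#' @return Integer-rounded percentage.
#' @export
percent_increase <- function(baseline, optimized) {
  stopifnot(is.numeric(baseline), is.numeric(optimized))
  if (any(baseline <= 0)) {
    stop("baseline value must be > 0", call. = FALSE)
  }
  round_half_up((optimized - baseline) / baseline * 100, 0)
}

#' Root-mean-square error between experimental and predicted values
#'
#' @param experimental,predicted Numeric vectors of equal length, >= 1 pair.
#' @return RMSE in ug/L.
#' @export
rmse <- function(experimental, predicted) {
  stopifnot(is.numeric(experimental), is.numeric(predicted),
            length(experimental) == length(predicted))
  if (length(experimental) == 0L) stop("rmse of an empty pair list", call. = FALSE)
  sqrt(mean((experimental - predicted)^2))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with explicit degeneracy checks: at
#' least two pairs and nonzero variance in both coordinates are required.
#'
#' @param experimental,predicted Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(experimental, predicted) {
  stopifnot(is.numeric(experimental), is.numeric(predicted),
            length(experimental) == length(predicted))
  if (length(experimental) < 2L) {
    stop("pearson_r needs at least 2 pairs", call. = FALSE)
  }
  if (stats::sd(experimental) == 0 || stats::sd(predicted) == 0) {
    stop("pearson_r undefined: zero variance in a coordinate", call. = FALSE)
  }
  stats::cor(experimental, predicted)
}

#' Build a validation report
#'
#' Computes the per-record percent variation and the aggregate metrics
#' (RMSE, Pearson correlation, range of the variations) from a table of
#' experimental/predicted riboflavin pairs. With a single record, or zero
#' variance in either coordinate, the correlation is undefined and
#' reported as `NA` while the rest of the report is still produced.
#'
#' @param records Data frame with columns `factor`, `level`, `predicted`,
#'   `experimental` (one row per validation fermentation).
#' @return A `validation_report`: list with `records` (the input plus a
#'   `percent_variation` column), `rmse`, `pearson_r` and
#'   `variation_range` (`c(min, max)` of the rounded variations).
#' @examples
#' fx <- riboflavin_reference()
#' validation_report(fx$pairs[fx$pairs$set == "validation", ])
#' @export
validation_report <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("factor", "level", "predicted", "experimental"),
                          names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("records lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no validation records", call. = FALSE)
  recs <- records[c("factor", "level", "predicted", "experimental")]
  recs$percent_variation <- percent_variation(recs$experimental, recs$predicted)
  r <- if (nrow(recs) >= 2L &&
           stats::sd(recs$experimental) > 0 && stats::sd(recs$predicted) > 0) {
    pearson_r(recs$experimental, recs$predicted)
  } else {
    NA_real_
  }
  structure(list(
    records = recs,
    rmse = rmse(recs$experimental, recs$predicted),
    pearson_r = r,
    variation_range = range(recs$percent_variation)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation of riboflavin predictions\n")
  print(x$records, row.names = FALSE)
  cat(sprintf("RMSE: %.4f ug/L   Pearson r: %s   variation range: %.2f%% to %.2f%%\n",
              x$rmse,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r),
              x$variation_range[1], x$variation_range[2]))
  invisible(x)
}

#' Write a validation report to CSV
#'
#' Columns, in order: factor, level, predicted, experimental,
#' percent_variation. The file can be re-read and every stored variation
#' recomputed from its own row.
#'
#' @param report A `validation_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.csv(report$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
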