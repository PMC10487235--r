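#' Induce fuzzy rules from an OFAT dose-response dataset
#'
#' Wang-Mendel one-pass rule generation. For every observation the
#' concentration and the response are fuzzified; the maximum-membership
#' term on each side forms a candidate rule (level term -> response term)
#' whose degree is the product of the two memberships. Among candidates
#' sharing an antecedent term the highest-degree consequent is kept; ties
#' are broken toward the lower-order consequent term (conservative: never
#' overstates predicted yield). Maximum-membership ties within one
#' observation also resolve to the lower-order term, so the procedure is
#' fully deterministic.
#'
#' Responses outside the output universe are clamped to the nearer edge
#' with a warning rather than rejected: unoptimized production sits near
#' the universe floor and noisy data occasionally cross it.
#'
#' @param dataset An [ofat_dataset()]; all levels must lie inside
#'   `input_var`'s universe.
#' @param input_var The `fuzzy_variable` of the dataset's factor.
#' @param output_var The response `fuzzy_variable` (riboflavin).
#' @return An `induced_rulebase`: list with `rules` (list of
#'   [fuzzy_rule()], ordered by antecedent term) and `provenance` (data
#'   frame recording, per observation, the fuzzified terms and degrees and
#'   whether its rule was kept).
#' @export
induce_rules <- function(dataset, input_var, output_var) {
  stopifnot(inherits(dataset, "ofat_dataset"),
            inherits(input_var, "fuzzy_variable"),
            inherits(output_var, "fuzzy_variable"))
  obs <- dataset$observations
  in_labels <- names(input_var$terms)
  out_labels <- names(output_var$terms)

  u <- output_var$universe
  resp <- pmin(pmax(obs$response, u[1]), u[2])
  n_clamped <- sum(resp != obs$response)
  if (n_clamped > 0L) {
    warning(sprintf(
      "%d response(s) outside the output universe [%g, %g] clamped to its edge",
      n_clamped, u[1], u[2]), call. = FALSE)
  }

  ant_deg <- t(vapply(obs$level, function(x) fuzzify(input_var, x),
                      numeric(length(in_labels))))
  cons_deg <- t(vapply(resp, function(y) fuzzify(output_var, y),
                       numeric(length(out_labels))))

  ant_idx <- apply(ant_deg, 1L, which.max)   # which.max -> first = lower order
  cons_idx <- apply(cons_deg, 1L, which.max)
  if (length(unique(ant_idx)) < 2L) {
    stop(errorCondition(
      sprintf("insufficient coverage: dataset for factor '%s' dominates only input term '%s'; need observations reaching >= 2 terms",
              dataset$factor, in_labels[ant_idx[1]]),
      class = c("ribofis_insufficient_coverage", "error", "condition")
    ))
  }
  a_deg <- ant_deg[cbind(seq_len(nrow(obs)), ant_idx)]
  c_deg <- cons_deg[cbind(seq_len(nrow(obs)), cons_idx)]
  degree <- a_deg * c_deg

  prov <- data.frame(
    obs = seq_len(nrow(obs)),
    level = obs$level,
    response = obs$response,
    antecedent_term = in_labels[ant_idx],
    consequent_term = out_labels[cons_idx],
    antecedent_degree = a_deg,
    consequent_degree = c_deg,
    degree = degree,
    kept = FALSE,
    stringsAsFactors = FALSE
  )

  rules <- list()
  for (ai in sort(unique(ant_idx))) {
    rows <- which(ant_idx == ai)
    best_deg <- max(degree[rows])
    best <- rows[degree[rows] == best_deg]
    winner <- best[which.min(cons_idx[best])]   # tie -> lower consequent term
    prov$kept[winner] <- TRUE
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      stats::setNames(in_labels[ai], input_var$name),
      out_labels[cons_idx[winner]]
    )
  }

  structure(list(rules = rules, provenance = prov, factor = dataset$factor),
            class = "induced_rulebase")
}

#' Induce rule bases for every factor
#'
#' Runs [induce_rules()] once per medium component, pairing each dataset
#' with its catalog variable and the riboflavin output. Exactly one dataset
#' per factor is required.
#'
#' @param datasets Named list of [ofat_dataset()]s covering all of
#'   `riboflavin_factors()`, with no duplicates.
#' @param catalog Variable catalog, default [riboflavin_variables()].
#' @return Named list of `induced_rulebase`s, one per factor, each ready
#'   for [build_single_factor_model()].
#' @export
induce_all <- function(datasets, catalog = riboflavin_variables()) {
  stopifnot(is.list(datasets))
  facs <- vapply(datasets, function(d) {
    stopifnot(inherits(d, "ofat_dataset")); d$factor
  }, character(1))
  if (anyDuplicated(facs)) {
    stop(sprintf("duplicate dataset(s) for factor '%s'",
                 facs[duplicated(facs)][1]), call. = FALSE)
  }
  missing_f <- setdiff(riboflavin_factors(), facs)
  if (length(missing_f) > 0L) {
    stop(sprintf("no dataset for factor(s): %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(riboflavin_factors(), function(f) {
    induce_rules(datasets[[which(facs == f)]], catalog[[f]], catalog$riboflavin)
  })
  names(out) <- riboflavin_factors()
  out
}

#' @export
print.induced_rulebase <- function(x, ...) {
  cat(sprintf("induced rule base (factor '%s'), %d rule(s):\n",
              x$factor, length(x$rules)))
  for (r in x$rules) {
    cat(sprintf("  IF %s is %s THEN riboflavin is %s\n",
                names(r$antecedent), r$antecedent, r$consequent))
  }
  invisible(x)
}

#' Write rule provenance to CSV
#'
#' Sidecar report for an induced rule base (or a named list of them):
#' per source observation, the fuzzified antecedent/consequent terms, the
#' membership degrees, the combined rule degree and whether the
#' observation's rule survived conflict resolution.
#'
#' @param rulebases An `induced_rulebase` or named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_provenance_csv <- function(rulebases, path) {
  if (inherits(rulebases, "induced_rulebase")) rulebases <- list(rulebases)
  rows <- lapply(rulebases, function(rb) {
    cbind(data.frame(factor = rb$factor, stringsAsFactors = FALSE),
          rb$provenance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
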