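# Model specification serialization (JSON). Round trips are lossless: the
# document carries variables with universes and term triples, rules as
# label mappings, operator names and grid size.

variable_to_list <- function(v) {
  list(
    name = v$name,
    universe = v$universe,
    terms = lapply(names(v$terms), function(lab) {
      mf <- v$terms[[lab]]
      list(label = lab, a = mf$a, b = mf$b, c = mf$c)
    })
  )
}

variable_from_list <- function(x) {
  terms <- lapply(x$terms, function(t) trimf(t$a, t$b, t$c))
  names(terms) <- vapply(x$terms, `[[`, character(1), "label")
  fuzzy_variable(x$name, unlist(x$universe), terms)
}

#' Write a Mamdani model to JSON
#'
#' @param model A `mamdani_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fis_json()]
#' @export
write_fis_json <- function(model, path) {
  stopifnot(inherits(model, "mamdani_model"))
  doc <- list(
    format = "ribofis-model",
    inputs = lapply(unname(model$inputs), variable_to_list),
    output = variable_to_list(model$output),
    rules = lapply(model$rules, function(r) {
      list(antecedent = as.list(r$antecedent), consequent = r$consequent,
           weight = r$weight)
    }),
    operators = model$operators,
    grid_points = model$grid_points
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Mamdani model from JSON
#'
#' @param path File written by [write_fis_json()].
#' @return A `mamdani_model`.
#' @export
read_fis_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' not found", path), call. = FALSE)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "ribofis-model")) {
    stop(sprintf("'%s' is not a ribofis model file", path), call. = FALSE)
  }
  rules <- lapply(doc$rules, function(r) {
    ant <- vapply(r$antecedent, as.character, character(1))
    fuzzy_rule(ant, r$consequent, if (is.null(r$weight)) 1 else r$weight)
  })
  mamdani_model(
    inputs = lapply(doc$inputs, variable_from_list),
    output = variable_from_list(doc$output),
    rules = rules,
    grid_points = doc$grid_points,
    operators = doc$operators
  )
}
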