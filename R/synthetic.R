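#' Dose-response curve for simulated fermentations
#'
#' Two-parameter families for the qualitative shapes seen in OFAT
#' riboflavin data: `"saturating"` (Hill with exponent 2) for components
#' whose effect plateaus at high dose (casamino acid, GTP) and
#' `"unimodal"` (Gaussian bump) for components with an interior optimum
#' followed by inhibition (glycine, sodium acetate).
#'
#' @param shape `"saturating"` or `"unimodal"`.
#' @param floor Response at the low end (ug/L); `340 <= floor < ceiling`.
#' @param ceiling Maximum response (ug/L); `<= 440` by default convention.
#' @param half_point Saturating only: dose (g/L) at which half the
#'   floor-to-ceiling rise is attained.
#' @param peak_location Unimodal only: dose (g/L) of the optimum.
#' @param width Unimodal only: Gaussian width (g/L), > 0.
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(shape = c("saturating", "unimodal"),
                           floor, ceiling,
                           half_point = NULL, peak_location = NULL,
                           width = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(floor), is.numeric(ceiling),
            length(floor) == 1L, length(ceiling) == 1L)
  if (!(floor < ceiling)) stop("need floor < ceiling", call. = FALSE)
  if (shape == "saturating") {
    if (is.null(half_point) || half_point <= 0) {
      stop("saturating curve needs half_point > 0", call. = FALSE)
    }
  } else {
    if (is.null(peak_location)) {
      stop("unimodal curve needs peak_location", call. = FALSE)
    }
    if (is.null(width) || width <= 0) {
      stop("unimodal curve needs width > 0", call. = FALSE)
    }
  }
  structure(list(shape = shape, floor = floor, ceiling = ceiling,
                 half_point = half_point, peak_location = peak_location,
                 width = width),
            class = "response_curve")
}

#' Noise-free response of a dose-response curve
#'
#' Saturating: `floor + (ceiling - floor) * level^2 / (level^2 + half_point^2)`.
#' Unimodal: `floor + (ceiling - floor) * exp(-(level - peak_location)^2 / (2 * width^2))`.
#' Deterministic; vectorized over `level`.
#'
#' @param curve A [response_curve()].
#' @param level Dose(s) in g/L.
#' @return Response(s) in ug/L, always within `[floor, ceiling]`.
#' @export
true_response <- function(curve, level) {
  stopifnot(inherits(curve, "response_curve"), is.numeric(level))
  span <- curve$ceiling - curve$floor
  if (curve$shape == "saturating") {
    curve$floor + span * level^2 / (level^2 + curve$half_point^2)
  } else {
    curve$floor + span * exp(-(level - curve$peak_location)^2 /
                               (2 * curve$width^2))
  }
}

#' Simulation configuration for synthetic OFAT experiments
#'
#' @param curves Named list of [response_curve()]s, one per factor.
#' @param levels Named list of numeric dose vectors, same factors; every
#'   level must lie inside the factor's universe when the factor belongs
#'   to the riboflavin catalog.
#' @param noise_sd Standard deviation of additive Gaussian measurement
#'   noise (ug/L), >= 0.
#' @param replicates Fermentation replicates per level, >= 1.
#' @param seed Mandatory RNG seed: every stochastic run must be replayable.
#' @return An object of class `simulation_config`.
#' @seealso [default_simulation_config()] for the study-condition defaults.
#' @export
simulation_config <- function(curves, levels, noise_sd = 3, replicates = 3L,
                              seed) {
  stopifnot(is.list(curves), is.list(levels))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit numeric seed is mandatory", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (!setequal(names(curves), names(levels)) || anyDuplicated(names(curves))) {
    stop("curves and levels must name the same factors", call. = FALSE)
  }
  cat <- riboflavin_variables()
  for (f in names(curves)) {
    if (!inherits(curves[[f]], "response_curve")) {
      stop(sprintf("curve for factor '%s' is not a response_curve", f),
           call. = FALSE)
    }
    lv <- levels[[f]]
    if (!is.numeric(lv) || length(lv) < 2L) {
      stop(sprintf("factor '%s' needs at least 2 levels", f), call. = FALSE)
    }
    if (f %in% names(cat)) {
      u <- cat[[f]]$universe
      if (any(lv < u[1] | lv > u[2])) {
        stop(sprintf("factor '%s': level outside its universe [%g, %g]",
                     f, u[1], u[2]), call. = FALSE)
      }
    }
  }
  structure(list(curves = curves, levels = levels, noise_sd = noise_sd,
                 replicates = replicates, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default study-condition simulation configuration
#'
#' Emulates the OFAT fermentation series the model is built from:
#' saturating casamino-acid and GTP curves (floor 346 ug/L, asymptotic
#' ceiling 432 ug/L, half-points 14 and 0.028 g/L — the same
#' dose/half-point ratios, since the GTP range is the casamino range
#' scaled by 0.002), unimodal sodium acetate (optimum 10 g/L, ceiling
#' 429 ug/L) and glycine (optimum 10 g/L, ceiling 425 ug/L), width
#' 2.5 g/L; the OFAT design doses (casamino 5/10/20, GTP 0.01/0.02/0.04,
#' sodium acetate and glycine 5/10/15 g/L); Gaussian noise of sd 3 ug/L;
#' triplicate fermentations.
#'
#' @param seed Mandatory RNG seed.
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(seed) {
  simulation_config(
    curves = list(
      casamino       = response_curve("saturating", 346, 432, half_point = 14),
      gtp            = response_curve("saturating", 346, 432, half_point = 0.028),
      sodium_acetate = response_curve("unimodal", 346, 429,
                                      peak_location = 10, width = 2.5),
      glycine        = response_curve("unimodal", 346, 425,
                                      peak_location = 10, width = 2.5)
    ),
    levels = list(
      casamino       = c(5, 10, 20),
      gtp            = c(0.01, 0.02, 0.04),
      sodium_acetate = c(5, 10, 15),
      glycine        = c(5, 10, 15)
    ),
    noise_sd = 3,
    replicates = 3L,
    seed = seed
  )
}

#' Generate synthetic OFAT datasets
#'
#' For every factor, level and replicate draws
#' `true_response(curve, level) + N(0, noise_sd)`, truncated below at zero
#' (responses are concentrations). Fully reproducible: the same
#' configuration, including its seed, yields identical datasets. The
#' caller's RNG state is restored on exit.
#'
#' @param config A [simulation_config()].
#' @return Named list of [ofat_dataset()]s, one per configured factor.
#' @export
generate_ofat <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  datasets <- lapply(names(config$curves), function(f) {
    lv <- config$levels[[f]]
    grid <- expand.grid(replicate = seq_len(config$replicates), level = lv)
    mu <- true_response(config$curves[[f]], grid$level)
    resp <- mu + stats::rnorm(nrow(grid), 0, config$noise_sd)
    resp <- pmax(resp, .Machine$double.eps)
    ofat_dataset(f, data.frame(level = grid$level, response = resp,
                               replicate = grid$replicate))
  })
  names(datasets) <- names(config$curves)
  datasets
}

#' Write a simulation configuration to JSON
#' @param config A [simulation_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  doc <- list(
    format = "ribofis-simulation",
    curves = lapply(config$curves, function(cv) {
      Filter(Negate(is.null), unclass(cv))
    }),
    levels = config$levels,
    noise_sd = config$noise_sd,
    replicates = config$replicates,
    seed = config$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation configuration from JSON
#' @param path File written by [write_simulation_config()].
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "ribofis-simulation")) {
    stop(sprintf("'%s' is not a ribofis simulation config", path), call. = FALSE)
  }
  curves <- lapply(doc$curves, function(cv) {
    response_curve(cv$shape, cv$floor, cv$ceiling,
                   half_point = cv$half_point,
                   peak_location = cv$peak_location,
                   width = cv$width)
  })
  simulation_config(curves = curves,
                    levels = lapply(doc$levels, function(x) unlist(x)),
                    noise_sd = doc$noise_sd,
                    replicates = doc$replicates,
                    seed = doc$seed)
}
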