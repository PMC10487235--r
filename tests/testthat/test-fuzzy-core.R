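test_that("triangular membership evaluates peaks, slopes, shoulders and support", {
  expect_equal(mf_degree(trimf(5, 12.5, 20), 12.5), 1)
  expect_equal(mf_degree(trimf(0, 5, 10), 2.5), 0.5)
  expect_equal(mf_degree(trimf(5, 5, 12.5), 5), 1)      # left shoulder
  expect_equal(mf_degree(trimf(5, 12.5, 12.5), 12.5), 1) # right shoulder
  expect_equal(mf_degree(trimf(5, 12.5, 20), 21), 0)
  expect_equal(mf_degree(trimf(5, 12.5, 20), 4), 0)
  # vectorized, degrees bounded
  x <- seq(-5, 30, by = 0.25)
  d <- mf_degree(trimf(5, 12.5, 20), x)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("invalid triangular geometry is rejected at construction", {
  expect_error(trimf(10, 5, 20), "a <= b <= c")
  expect_error(trimf(5, 5, 5), "zero-width")
  expect_error(trimf(5, NA, 20))
})

test_that("fuzzify returns per-term degrees and rejects out-of-range values", {
  cat <- riboflavin_variables()
  expect_equal(unname(fuzzify(cat$casamino, 12.5)), c(0, 1, 0))
  expect_equal(unname(fuzzify(cat$casamino, 8.75)), c(0.5, 0.5, 0))
  expect_equal(unname(fuzzify(cat$sodium_acetate, 5)), c(1, 0, 0))
  err <- expect_error(fuzzify(cat$casamino, 25), class = "ribofis_out_of_range")
  expect_match(conditionMessage(err), "casamino")
  expect_match(conditionMessage(err), "\\[5, 20\\]")
})

test_that("fuzzy_variable validation enforces universe, ordering and coverage", {
  expect_error(fuzzy_variable("v", c(1, 1), list(a = trimf(0, 0.5, 1))),
               "umin < umax")
  # support outside universe
  expect_error(fuzzy_variable("v", c(0, 1), list(a = trimf(-0.5, 0, 1))),
               "exceeds universe")
  # non-increasing peaks
  expect_error(
    fuzzy_variable("v", c(0, 1),
                   list(a = trimf(0, 0.6, 1), b = trimf(0, 0.4, 1))),
    "strictly increase")
  # coverage gap in the middle
  expect_error(
    fuzzy_variable("v", c(0, 10),
                   list(a = trimf(0, 0, 2), b = trimf(8, 10, 10))),
    "cover")
})

test_that("firing strength is min over antecedents times weight", {
  cat <- riboflavin_variables()
  model <- mamdani_model(
    inputs = cat[c("casamino", "gtp")],
    output = cat$riboflavin,
    rules = list(
      fuzzy_rule(c(casamino = "medium"), "medium"),
      fuzzy_rule(c(casamino = "low", gtp = "high"), "high"),
      fuzzy_rule(c(casamino = "high"), "high", weight = 0.5)
    )
  )
  # peak membership
  expect_equal(firing_strength(model$rules[[1]], list(casamino = 12.5), model), 1)
  # min of 0.4 (casamino low at 9.5) and 0.7 (gtp high at 0.0355)
  expect_equal(
    firing_strength(model$rules[[2]], list(casamino = 9.5, gtp = 0.0355), model),
    0.4)
  # a zero-membership antecedent kills the rule
  expect_equal(
    firing_strength(model$rules[[2]], list(casamino = 20, gtp = 0.0355), model),
    0)
  # weight scales the strength
  expect_equal(firing_strength(model$rules[[3]], list(casamino = 20), model), 0.5)
  # missing input is a named error
  expect_error(firing_strength(model$rules[[2]], list(casamino = 9.5), model),
               "gtp")
})

test_that("model construction rejects unknown references and conflicts", {
  cat <- riboflavin_variables()
  expect_error(
    mamdani_model(cat["casamino"], cat$riboflavin,
                  list(fuzzy_rule(c(nope = "low"), "low"))),
    "unknown input variable")
  expect_error(
    mamdani_model(cat["casamino"], cat$riboflavin,
                  list(fuzzy_rule(c(casamino = "tiny"), "low"))),
    "unknown term")
  expect_error(
    mamdani_model(cat["casamino"], cat$riboflavin,
                  list(fuzzy_rule(c(casamino = "low"), "huge"))),
    "unknown output term")
  expect_error(
    mamdani_model(cat["casamino"], cat$riboflavin,
                  list(fuzzy_rule(c(casamino = "low"), "low"),
                       fuzzy_rule(c(casamino = "low"), "high"))),
    "conflicting rules")
  expect_error(
    mamdani_model(cat["casamino"], cat$riboflavin, list()),
    "at least one rule")
  expect_error(fuzzy_rule(c(casamino = "low"), "low", weight = 0), "weight")
})

test_that("inference aggregates clipped consequents and flags silent surfaces", {
  model <- controlled_firing_model()
  out_terms <- riboflavin_variables()$riboflavin$terms

  # one rule firing at strength 1: surface equals that triangle on the grid
  agg <- infer(model, controlled_inputs(c(0, 1, 0)))
  expect_equal(agg$degrees, mf_degree(out_terms$medium, agg$grid))

  # two rules at 0.5 each with disjoint consequents: pointwise max of clips
  agg2 <- infer(model, controlled_inputs(c(0.5, 0, 0.5)))
  expected <- pmax(pmin(0.5, mf_degree(out_terms$low, agg2$grid)),
                   pmin(0.5, mf_degree(out_terms$high, agg2$grid)))
  expect_equal(agg2$degrees, expected)
  expect_true(all(agg2$degrees >= 0 & agg2$degrees <= 1))
  expect_equal(length(agg2$grid), length(agg2$degrees))

  # zero strength everywhere is an error, not a zero surface
  expect_error(infer(model, controlled_inputs(c(0, 0, 0))),
               class = "ribofis_no_rule_fired")
})

test_that("centroid defuzzification respects symmetry and the uniform case", {
  model <- controlled_firing_model()
  # symmetric medium triangle clipped at any height -> 390
  for (s in c(0.2, 0.6, 1)) {
    expect_equal(predict(model, controlled_inputs(c(0, s, 0))), 390,
                 tolerance = 1e-12)
  }
  # constant-1 surface over [340, 440] -> 390
  flat <- structure(list(grid = seq(340, 440, length.out = 1001),
                         degrees = rep(1, 1001)),
                    class = "aggregated_output")
  expect_equal(defuzzify_centroid(flat), 390)
  # result lies within the support of the surface
  agg <- infer(model, controlled_inputs(c(1, 0, 0)))
  v <- defuzzify_centroid(agg)
  expect_gte(v, min(agg$grid[agg$degrees > 0]))
  expect_lte(v, max(agg$grid[agg$degrees > 0]))
})

test_that("centroid agrees with a 10x-resolution Riemann-sum oracle", {
  model <- controlled_firing_model()
  mfs <- lapply(riboflavin_variables()$riboflavin$terms,
                function(mf) c(mf$a, mf$b, mf$c))
  set.seed(42)
  for (i in 1:100) {
    s <- runif(3)
    s[sample(3, 1)] <- runif(1, 0.3, 1)  # ensure a solidly fired rule
    got <- predict(model, controlled_inputs(s))
    want <- oracle_centroid(
      list(list(s = s[1], mf = mfs$low),
           list(s = s[2], mf = mfs$medium),
           list(s = s[3], mf = mfs$high)),
      universe = c(340, 440), n = 10001L)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("identical consequents give that consequent's centroid at any input", {
  model <- build_single_factor_model("casamino", list(
    fuzzy_rule(c(casamino = "low"), "medium"),
    fuzzy_rule(c(casamino = "medium"), "medium"),
    fuzzy_rule(c(casamino = "high"), "medium")
  ))
  for (x in c(5, 7.3, 12.5, 16, 20)) {
    expect_equal(predict(model, list(casamino = x)), 390, tolerance = 1e-12)
  }
})

test_that("prediction is deterministic and accepts data-frame input", {
  model <- monotone_casamino_model()
  a <- predict(model, list(casamino = 9.7))
  b <- predict(model, list(casamino = 9.7))
  expect_identical(a, b)
  df <- data.frame(casamino = c(5, 9.7, 20))
  expect_identical(predict(model, df)[2], a)
})

test_that("model JSON serialization round-trips losslessly", {
  model <- mamdani_model(
    inputs = riboflavin_variables()[c("casamino", "gtp")],
    output = riboflavin_variables()$riboflavin,
    rules = list(
      fuzzy_rule(c(casamino = "low", gtp = "high"), "medium", weight = 0.75),
      fuzzy_rule(c(casamino = "high"), "high")
    ),
    grid_points = 501L
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_fis_json(model, path)
  back <- read_fis_json(path)
  expect_equal(back, model)
  # and load -> save -> load is stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_fis_json(back, path2)
  expect_equal(read_fis_json(path2), model)
  # predictions are bit-identical through the round trip
  inp <- list(casamino = 8.2, gtp = 0.033)
  expect_identical(predict(back, inp), predict(model, inp))
})
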