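cat_vars <- riboflavin_variables()

test_that("peak-anchored observations induce the peak-pair rules", {
  d <- ofat_dataset("casamino",
                    data.frame(level = c(5, 12.5, 20),
                               response = c(342, 392, 438)))
  rb <- induce_rules(d, cat_vars$casamino, cat_vars$riboflavin)
  got <- vapply(rb$rules, function(r) {
    paste(r$antecedent, r$consequent, sep = "->")
  }, character(1))
  expect_equal(got, c("low->low", "medium->medium", "high->high"))
  expect_true(all(rb$provenance$degree > 0 & rb$provenance$degree <= 1))
  expect_equal(sum(rb$provenance$kept), 3L)
})

test_that("antecedent conflicts resolve to the highest-degree consequent", {
  # both observations max out the medium antecedent; consequents differ:
  # 345 -> low at degree 0.9, 420 -> high at degree 0.6
  d <- ofat_dataset("casamino",
                    data.frame(level = c(12.5, 12.4, 5),
                               response = c(345, 420, 350)))
  rb <- induce_rules(d, cat_vars$casamino, cat_vars$riboflavin)
  med <- Filter(function(r) r$antecedent == "medium", rb$rules)
  expect_length(med, 1L)
  expect_equal(med[[1]]$consequent, "low")
  kept <- rb$provenance[rb$provenance$kept &
                          rb$provenance$antecedent_term == "medium", ]
  expect_equal(kept$response, 345)
})

test_that("degree ties break toward the lower-order consequent term", {
  # both level-12.5 observations fire the medium antecedent at 1; response
  # 360 maxes the low output term at 0.6 and response 420 the high term at
  # 0.6 - an exact cross-observation degree tie with distinct consequents
  d <- ofat_dataset("casamino",
                    data.frame(level = c(12.5, 12.5, 5),
                               response = c(360, 420, 350),
                               replicate = c(1L, 2L, 1L)))
  rb <- induce_rules(d, cat_vars$casamino, cat_vars$riboflavin)
  med <- Filter(function(r) r$antecedent == "medium", rb$rules)
  expect_length(med, 1L)
  expect_equal(med[[1]]$consequent, "low")
})

test_that("responses outside the output universe are clamped with a warning", {
  d <- ofat_dataset("casamino",
                    data.frame(level = c(5, 12.5, 20),
                               response = c(335, 392, 445)))
  expect_warning(
    rb <- induce_rules(d, cat_vars$casamino, cat_vars$riboflavin),
    "clamped")
  labs <- vapply(rb$rules, `[[`, character(1), "consequent")
  expect_equal(labs, c("low", "medium", "high"))
})

test_that("datasets dominating a single input term are rejected", {
  d <- ofat_dataset("casamino",
                    data.frame(level = c(12.4, 12.5), response = c(390, 391)))
  expect_error(induce_rules(d, cat_vars$casamino, cat_vars$riboflavin),
               class = "ribofis_insufficient_coverage")
})

test_that("induce_all requires exactly one dataset per factor", {
  cfg <- peak_level_config(seed = 7)
  datasets <- generate_ofat(cfg)
  rbs <- induce_all(datasets)
  expect_named(rbs, riboflavin_factors())
  expect_true(all(vapply(rbs, function(rb) length(rb$rules), integer(1)) >= 2L))

  expect_error(induce_all(datasets[c("casamino", "gtp")]), "sodium_acetate")
  expect_error(induce_all(c(datasets, list(extra = datasets$casamino))),
               "duplicate")
})

test_that("noiseless generation from known rules is recovered exactly", {
  # observations placed at the peak pairs implied by each rule base
  rule_sets <- list(
    c(low = "low", medium = "medium", high = "high"),
    c(low = "low", medium = "high", high = "high"),
    c(low = "medium", medium = "medium", high = "high")
  )
  out_peaks <- c(low = 340, medium = 390, high = 440)
  in_peaks <- c(low = 5, medium = 12.5, high = 20)
  for (rs in rule_sets) {
    d <- ofat_dataset("casamino",
                      data.frame(level = unname(in_peaks[names(rs)]),
                                 response = unname(out_peaks[rs])))
    rb <- induce_rules(d, cat_vars$casamino, cat_vars$riboflavin)
    got <- stats::setNames(
      vapply(rb$rules, `[[`, character(1), "consequent"),
      vapply(rb$rules, function(r) unname(r$antecedent), character(1)))
    expect_equal(got[names(rs)], rs)
  }
})

test_that("on peak-anchored data predictions equal the consequent centroid", {
  d <- ofat_dataset("glycine",
                    data.frame(level = c(5, 10, 15),
                               response = c(356, 428, 357)))
  rb <- induce_rules(d, cat_vars$glycine, cat_vars$riboflavin)
  model <- build_single_factor_model("glycine", rb)
  grid_step <- diff(cat_vars$riboflavin$universe) / (model$grid_points - 1)
  for (r in rb$rules) {
    lev <- cat_vars$glycine$terms[[unname(r$antecedent)]]$b
    cons_mf <- cat_vars$riboflavin$terms[[r$consequent]]
    grid <- seq(340, 440, length.out = model$grid_points)
    deg <- mf_degree(cons_mf, grid)
    centroid <- sum(grid * deg) / sum(deg)
    expect_lte(abs(predict(model, stats::setNames(list(lev), "glycine")) -
                     centroid),
               grid_step)
  }
})
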