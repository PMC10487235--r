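# Independent oracles and small builders shared across test files.

# Triangle membership written from the defining formula, independent of
# the package's mf_degree (no shared code path).
oracle_tri <- function(a, b, c, x) {
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
  pmax(0, pmin(up, dn, 1))
}

# Riemann-sum centroid of a max-of-clipped-triangles surface on a fine
# grid: firings is a list of list(s = strength, mf = c(a, b, c)).
oracle_centroid <- function(firings, universe, n = 10001L) {
  y <- seq(universe[1], universe[2], length.out = n)
  mu <- rep(0, n)
  for (f in firings) {
    mu <- pmax(mu, pmin(f$s, oracle_tri(f$mf[1], f$mf[2], f$mf[3], y)))
  }
  sum(y * mu) / sum(mu)
}

# Direct-formula Pearson correlation (covariance over product of sds),
# independent of stats::cor.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))

# Three-input model whose rules fire at exactly the strengths supplied:
# each input is a three-term variable on [0, 1] with medium peak 0.5, so
# "xi is medium" has membership 2*v on v in [0, 0.5]. Setting xi = s/2
# fires rule i at strength s. Consequents are the three riboflavin terms.
controlled_firing_model <- function(grid_points = 1001L) {
  inputs <- lapply(1:3, function(i) {
    three_term_variable(paste0("x", i), 0, 0.5, 1)
  })
  rules <- list(
    fuzzy_rule(c(x1 = "medium"), "low"),
    fuzzy_rule(c(x2 = "medium"), "medium"),
    fuzzy_rule(c(x3 = "medium"), "high")
  )
  mamdani_model(inputs, riboflavin_variables()$riboflavin, rules,
                grid_points = grid_points)
}

# Inputs that make controlled_firing_model fire its three rules at
# strengths s (vector of 3 values in [0, 1]).
controlled_inputs <- function(s) list(x1 = s[1] / 2, x2 = s[2] / 2, x3 = s[3] / 2)

# Order-preserving single-factor casamino model used in several tests.
monotone_casamino_model <- function() {
  build_single_factor_model("casamino", list(
    fuzzy_rule(c(casamino = "low"), "low"),
    fuzzy_rule(c(casamino = "medium"), "medium"),
    fuzzy_rule(c(casamino = "high"), "high")
  ))
}

# Peak-anchored simulation config: default curves, doses at the
# membership-function peaks of each factor.
peak_level_config <- function(seed, noise_sd = 0, replicates = 1L) {
  cfg <- default_simulation_config(seed)
  cfg$levels <- list(
    casamino = c(5, 12.5, 20),
    gtp = c(0.01, 0.025, 0.04),
    sodium_acetate = c(5, 10, 15),
    glycine = c(5, 10, 15)
  )
  cfg$noise_sd <- noise_sd
  cfg$replicates <- as.integer(replicates)
  cfg
}
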