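---
title: "Methods: Mamdani fuzzy inference for OFAT riboflavin data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mamdani fuzzy inference for OFAT riboflavin data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofis)
```

## The modelling problem

Riboflavin-overproducing lactic acid bacteria respond dose-dependently to
several components of a semi-defined fermentation medium. The available
evidence is one-factor-at-a-time (OFAT): each series varies a single
component — casamino acid, GTP, sodium acetate or glycine — while the
others stay at baseline, and reports riboflavin (µg/L) per dose. OFAT data
are sparse (a handful of doses, a few replicates) and carry no information
about interactions, which makes heavy parametric response-surface models
hard to justify. A Mamdani fuzzy inference system is a natural fit: it
encodes the dose–response relationship as a small set of interpretable
linguistic rules ("IF casamino is high THEN riboflavin is medium"), needs
no functional form, and degrades gracefully between observed doses.

`ribofis` implements the full chain: linguistic variables → rule induction
from OFAT tables → Mamdani inference → validation metrics, plus a
synthetic OFAT generator so that every stage is testable without wet-lab
data.

## Variables and membership functions

All variables use triangular membership functions with three ordered terms.
The construction is peak-anchored: for peaks $u_{\min} < m < u_{\max}$,

* low $= (u_{\min}, u_{\min}, m)$ — a left shoulder,
* medium $= (u_{\min}, m, u_{\max})$,
* high $= (m, u_{\max}, u_{\max})$ — a right shoulder.

Adjacent terms share feet at each other's peaks, which buys two properties
the engine relies on: *coverage* (no dose ever has zero membership
everywhere, so a complete rule base always fires) and *partition of unity*
(the three memberships sum to exactly 1, so fuzzification is a convex
re-coding of the dose). Both are enforced at construction time and
re-checked by property tests at 1001 universe points (tolerance $10^{-9}$;
the arithmetic is exact up to floating-point rounding).

The catalog (`riboflavin_variables()`): casamino acid 5–20 g/L with peaks
5 / 12.5 / 20; GTP 0.01–0.04 g/L with peaks 0.01 / 0.025 / 0.04; sodium
acetate and glycine 5–15 g/L with peaks 5 / 10 / 15; riboflavin output
340–440 µg/L with peaks 340 / 390 / 440. Two placements were genuinely
open and are package decisions: the GTP medium peak (0.025 g/L, the range
midpoint, by analogy with the explicitly midpoint mediums of the other
inputs) and the output peaks (edge-and-midpoint placement, the same
construction every input uses). ppb and µg/L are treated as the same unit,
as is standard for dilute aqueous media. Casamino doses below 5 g/L that
appear in some OFAT designs fall outside the model's universe and are
rejected, not clamped — the fuzzy model is only defined on its stated
ranges, and silent clamping would fabricate predictions at doses the rule
base knows nothing about.

## Inference and its numerical choices

Operators are the classical Mamdani triple: minimum AND, minimum
implication, maximum aggregation. The defuzzifier is the discrete centroid
over an equally spaced output grid. None of these is forced by the data —
they are the standard toolbox defaults, the centroid being the only common
choice whose value on a symmetric clipped output set is the set's centre
(a sanity anchor the tests use). The operator record is stored on the
model so alternatives could be added without changing the serialized
format.

* **Grid**: 1001 points over 340–440 µg/L, i.e. 0.1 µg/L resolution — an
  order of magnitude below any reported prediction-vs-experiment
  difference. Tests compare the discrete centroid against a 10×-finer
  Riemann-sum oracle written independently in the test code; agreement is
  required to 0.1% relative error over random rule firings.
* **"No rule fired" is an error**, carried as a classed condition
  (`ribofis_no_rule_fired`), not a zero: a defuzzified 0 would lie far
  outside the output universe and silently corrupt validation tables.
  With the bundled three-term variables and a complete induced rule base
  this cannot happen for in-range inputs; it protects hand-written rule
  bases.
* **Determinism**: inference involves no randomness; identical model and
  inputs give bit-identical predictions, and model JSON round-trips are
  lossless, which the tests assert with `identical()`.

A single-factor model and the joint four-input model agree exactly when
the rule base only constrains that factor, because variables a rule does
not mention cannot change its firing strength. Whether the original
toolbox study used four separate single-input models or one joint model
with baselines is not recoverable; both are provided and tested for this
equivalence.

## Rule induction

The rule base behind a published fuzzy model is often shown only as a
toolbox screenshot, so `induce_rules()` reconstructs rules from the data
by Wang–Mendel one-pass generation: fuzzify each observation's dose and
response, take the maximum-membership term on each side, and form the rule
*dose-term → response-term* with degree equal to the product of the two
memberships. Conflicting rules for one antecedent keep the
highest-degree consequent. Two tie-breaks make the procedure fully
deterministic: maximum-membership ties within an observation and degree
ties across observations both resolve to the lower-order term. The
lower-order choice is conservative — it never overstates predicted yield.
Responses outside 340–440 µg/L are clamped to the universe edge with a
warning (unoptimized baselines sit near the floor, and noisy replicates
occasionally cross it); doses outside the universe remain errors. A
dataset whose doses all max out a single term would induce a one-rule
base that cannot interpolate, and is rejected as insufficient coverage.
Every kept and discarded vote is recorded in a provenance table.

## The synthetic OFAT generator

`generate_ofat()` stands in for fermentation runs. Each factor gets a
deterministic dose–response curve plus additive Gaussian measurement
noise, truncated below zero. Two curve families cover the qualitative
shapes seen in this system:

* **saturating** (casamino acid, GTP): Hill with exponent 2,
  $f(x) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})\,
  x^2 / (x^2 + h^2)$;
* **unimodal** (glycine, sodium acetate): Gaussian bump,
  $f(x) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})\,
  e^{-(x - p)^2 / 2w^2}$.

The defaults (`default_simulation_config()`) are anchored to the reported
behaviour of this strain and medium: floors at 346 µg/L (the unoptimized
production), a sodium acetate optimum at 10 g/L reaching 429 µg/L (the
reported maximum), a glycine optimum at 10 g/L reaching 425 µg/L, width
2.5 g/L for both bumps, and saturating curves with asymptotic ceiling
432 µg/L and half-point 14 g/L for casamino — which puts the response at
20 g/L at +16.7% over baseline, the reported casamino gain. The GTP
half-point is 0.028 g/L, the casamino value scaled by the ratio of the
dose ranges, so both saturating factors traverse the same relative curve.
Noise sd is 3 µg/L with triplicate fermentations: symmetric replicate
error at roughly 4% of the ~80 µg/L dynamic range, consistent with
mean-±-SD reporting conventions. Doses default to the OFAT design
(casamino 5/10/20, GTP 0.01/0.02/0.04, the others 5/10/15 g/L). The seed
is mandatory; there is no implicit RNG state.

These choices were fixed once, from the published qualitative anchors, and
the tests are run against them rather than the other way round.

What the generator does *not* emulate: growth kinetics and their coupling
to dose, non-Gaussian or dose-dependent measurement error, batch effects
between OFAT series, interactions between components (OFAT itself cannot
see them), and time/temperature/pH effects. A passing round-trip test
therefore shows that the pipeline recovers the rules and magnitudes of
clean dose–response structure — not that real fermentations obey these
curve families.

Two quantitative consequences of the design are worth stating. First, a
Wang–Mendel model quantizes: at a training dose sitting on a membership
peak, the prediction is the centroid of a single clipped output term
(≈356.7, 390 or 423.3 µg/L). The round-trip test's 15 µg/L bound is this
membership-grid quantization bound, not a claim of continuous accuracy.
Second, rule stability under noise depends on how far true responses sit
from the output-term crossovers (365 and 415 µg/L); with the default
curves the nearest approach is ≈7.8 µg/L (2.6 noise sd), and a stochastic
regression test checks that 200 seeded noisy replications reproduce the
noiseless rule bases in at least 95% of trials.

## Validation arithmetic

`percent_variation()` is $(\mathrm{experimental} - \mathrm{predicted}) /
\mathrm{experimental} \times 100$, rounded half-up (away from zero) to two
decimals — the only sign convention that reproduces all four bundled
reference variations (0.75, 0.29, 0.82, −0.61) from their printed inputs;
the headline improvement $(\mathrm{optimized} - \mathrm{baseline}) /
\mathrm{baseline} \times 100$ rounds half-up to an integer (346 → 429 µg/L
gives 24). Half-up is implemented explicitly because R's `round()` uses
banker's rounding. RMSE and Pearson correlation are computed on whatever
pairs the report is given; the full point set behind the original model's
published RMSE/R is not available, so the package makes no claim of
reproducing those two numbers and the report carries its own values
(RMSE 2.5043 µg/L and r 0.9666 on the four bundled reference pairs).
With a single record the correlation is undefined and reported as `NA`
rather than an error, so one-row reports still aggregate.

## Problem sizes

The shipped tests and the acceptance script run at the scale the methods
naturally occupy: OFAT designs of 3 doses × 3 replicates × 4 factors,
1001-point output grids, 100-draw oracle comparisons, 1000-input
boundedness sweeps, 200-trial noise-stability replications and a
10,000-replicate convergence check — a few seconds end to end on one core.

## Known limitations

* The induced rule base approximates the original study's (graphical-only)
  rules via dose–response behaviour; exact rule recovery is untestable.
* Triangular, three-term variables only; no Gaussian/trapezoidal sets,
  Sugeno inference, or membership-parameter tuning.
* OFAT data cannot inform cross-factor rules, so joint models built from
  OFAT-induced rules are additive in behaviour even though the engine
  supports multi-antecedent rules.
* Out-of-universe doses are rejected; users wanting extrapolation must
  widen the variable universes deliberately.
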