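---
title: "From dietary standards to meals: models and methods in mealforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dietary standards to meals: models and methods in mealforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mealforge)
```

mealforge turns per-day dietary reference values into concrete meals. It
works in five stages: (1) discover *meal archetypes* — recurring meal
patterns such as cereal bowls or sandwich plates — by density-based
clustering of a meal corpus; (2) generate new food combinations with a
conditional variational autoencoder (CVAE) conditioned on archetype and
meal type; (3) assign gram portions so each meal meets its share of the
daily Recommended Daily Intake (RDI) targets; (4) score meals with
standard adequacy and moderation metrics; and (5) recommend few-item
substitutions along a nutrition-versus-cost frontier. A seeded synthetic
corpus generator stands in for dietary-survey data so the whole pipeline
is reproducible from code alone. This vignette records the models, the
parameters that matter, and the design decisions behind them.

## The synthetic corpus generator

`generate_catalog()` creates foods with per-gram densities for a fixed
20-nutrient panel (4 macronutrients, 11 micronutrients, 5 limit
nutrients) plus energy. Energy is Atwater-consistent by construction:
within 5% of `4*protein + 4*carbohydrate + 9*fat` kcal/g. One category is
always `beverages`, dilute by design (mean energy density about 0.4
kcal/g), because beverage-specific portion constraints must be
exercisable.

`archetype_specs()` defines meal archetypes as distributions: a
category-weight simplex with a dominant category, item count
`1 + Poisson(lambda)` (default `lambda = 3`, so four items on average),
lognormal gram draws per category (`sdlog = 0.4`), and Zipf food
popularity within category (`s = 1.2`). Heavy-tailed popularity and
sparse meals mirror real intake data. Three generator choices deserve
comment:

* **Beverages accompany, never dominate.** Archetype dominant categories
  cycle over the solid categories only; beverages receive a small fixed
  weight (default 0.08, halved into the remaining mass when dominance is
  extreme) and 240 g typical portions. A beverage-dominated "archetype"
  would be an artifact no survey reports.
* **Dominant categories are entree-scaled.** The dominant category draws
  its per-item gram scale from 90-160 g. Without this, archetypes built
  on garnish-scale categories (condiments at 40 g/item) produce meals so
  small that all of them collapse into one low-energy blob.
* **Quality nutrients sit near, not far above, their limits.** Sodium,
  saturated fat and sugar densities are calibrated so a typical
  2,000-kcal day of synthetic food lands in the neighbourhood of the
  daily limits. This matches population intake patterns and keeps the
  portion optimizer's energy-versus-limit trade-off realistic rather
  than degenerate.

`synthetic_benchmark()` fixes the evaluation scene used throughout the
package's tests: 2,000 meals, 200 foods in 10 categories, 4 archetypes
per meal type, and archetype dominance 0.95. The high dominance is
deliberate: the recoverability property ("clustering finds the planted
archetypes") is only meaningful when the planted structure is genuinely
well-separated, and at the generic default dominance of 0.75 even a
supervised k-means with the true k only reaches ARI about 0.7 — that
regime is not separable, so no density clusterer should be expected to
recover it.

What the generator does **not** emulate: survey weights, respondent
demographics, real food-code hierarchies, seasonal or regional intake
structure, and correlated nutrient profiles within brands. Tests passing
on this corpus show the machinery is correct and calibrated at desk
scale; they do not certify performance on survey data.

## Preprocessing

* **Code harmonization** (`harmonize_codes()`) follows mapping chains
  transitively (cycles are an error), replaces expanded / consolidated /
  renumbered codes, keeps dropped and revised codes, and merges
  duplicate foods within a meal by summing grams. It is idempotent.
* **Outlier removal** (`lof_filter()`) implements the Local Outlier
  Factor from first principles (k-distance, reachability, local
  reachability density) and removes exactly `round(contamination * n)`
  meals, most extreme first; the default contamination is 0.003. LOF
  runs on the same hybrid features as clustering, with neighbourhood
  size 20; the features and k are our choice since no standard is fixed
  for this step.
* **Prototype aggregation** (`aggregate_prototypes()`) compresses the
  food space per subcategory by greedy facility location: prototypes are
  added until gram-weighted mass coverage reaches 0.90 *and* nutrient
  fidelity error falls to 0.07; each food then joins its nearest
  prototype by nutrient-density cosine similarity if that similarity is
  at least 0.70, otherwise it stays its own prototype. The greedy
  solution carries the usual (1 - 1/e) guarantee for the submodular
  coverage objective, and the self-prototyping fallback makes the
  thresholds unconditionally attainable. Fidelity defaults to MARE (mean
  absolute relative error of the prototype-reconstructed nutrient
  totals); a weighted cosine error is available. Ties always break
  lexicographically by food code.
* **Bootstrap ingredient filtering**
  (`bootstrap_ingredient_filter()`) computes a percentile bootstrap CI
  for each food's mean presence and removes foods whose lower bound does
  not exceed a threshold. The comparison value is not fixed by any
  external standard; we use 0 — the only parameter-free reading: a food
  is dropped exactly when the bootstrap cannot bound its prevalence away
  from zero — and expose it as a parameter.

## Archetype discovery

Meals are embedded in a hybrid feature space: nutrient totals and ratio
features (macro energy shares, energy density, fiber per 1,000 kcal,
macro diversity as the Shannon-exponential Hill number, and a meal
balance score defined as 1 minus the Gini coefficient of the macro
energy shares — one of several reasonable formalizations of "balance"),
plus a category block with grams per main and subcategory *and each main
category's share of total meal grams*. The share features are a
deliberate extension: item-count variance makes within-archetype
meal-size spread larger than between-archetype distances in absolute
gram space, which merges density modes; composition shares factor meal
size out and make the planted structure recoverable. All features are
z-scored within meal type; zero-variance columns map to 0.

Clustering is an HDBSCAN*-style procedure implemented in the package:
core distances at `min_samples` neighbours, mutual-reachability
distances, a single-linkage hierarchy, a condensed tree at
`min_cluster_size`, and excess-of-mass cluster selection (the root is
eligible only when the tree never splits, so a single blob yields a
single cluster). Post-processing merges cluster pairs whose z-space
centroids have cosine similarity at least 0.95, most similar first. We
expose `min_cluster_size` (default `max(15, n/200)`) and `min_samples`
(default 5); a selection-epsilon knob is not offered because the
condensed-tree selection here is pure excess-of-mass.

Noise is a feature, not a failure: on the benchmark, 12-23% of meals —
dominated by 1-2-item meals that genuinely carry no archetype signal —
are left unassigned, and recovery is therefore measured as ARI against
the planted archetypes over the *assigned* meals (0.98-1.0 on the
benchmark), alongside the assigned fraction. Profiling contrasts each
cluster against its complement with Welch t-tests, Benjamini-Hochberg
correction at q <= 0.01, an absolute z-scale mean difference of at
least 0.15 for significance, 0.20 for "distinctive", and pooled-SD
Cohen's d; clusters smaller than 3 are marked unstable and not tested.

## The conditional VAE

The generator models binary food-presence vectors. Encoder and decoder
are stacks of three GELU blocks conditioned by FiLM: each block's
pre-activation is scaled and shifted (`gamma * h + beta`) by linear maps
of the concatenated cluster and meal-type embeddings (8 dimensions
each). The latent is a 64-dimensional diagonal Gaussian. Two
pair-specific devices sharpen generation: a prior that adds each
(cluster, meal-type) pair's food prevalence log-odds (clipped to stay
finite) to the decoder logits, and an allowed-foods gate — the top-k
foods by within-pair prevalence, k the pair's median item count — that
subtracts `mask_strength = 12` from disallowed logits at sampling time.
The gate constrains *which* foods may be sampled; the expected item
count is calibrated on the ungated probabilities, so gating does not
bias counts downward.

Training is plain base-R matrix code with manual backpropagation: Adam
(learning rate 5e-4), global-norm gradient clipping at 0.5, weighted BCE
with a per-batch positive-class weight `#neg/#pos` clipped to [1, 50], a
free-bits KL floor of 0.05 nats per latent dimension, a beta schedule
that ramps linearly to `beta_max` over 5 warmup epochs and then cycles
triangularly between `beta_max` and `0.1 * beta_max` in 10-epoch legs,
and a count-matching term (squared error between the summed
probabilities and the true item count). Reconstruction is deterministic:
z is the posterior mean, and the decoded set is the top-m foods with
`m = round(sum of probabilities)`. A Bernoulli decode is available by
configuration.

The benchmark configuration (`cvae_benchmark_config()`) uses width 128
(three blocks) and 500 epochs with `beta_max = 0.2` — a desk-scale
setting chosen so a full benchmark fit takes minutes on one CPU; the
package default keeps the reference width of 512. On the benchmark
(2,000 meals, 400 held out), held-out reconstruction micro-F1 is about
0.91, and disabling conditioning (no FiLM inputs, no pair prior, no
gate) at a matched budget drops it to about 0.69 — the ablation
contract is a strict decrease. Lower `beta_max` favours reconstruction
fidelity over latent smoothness; at 0.2 the KL term still keeps the
aggregate posterior usable for prior sampling.

## Portion assignment

Each meal type owns a fixed share of the 2,000-kcal daily targets:
breakfast 25%, lunch 35%, dinner 40%; all RDI and limit values scale by
the same share. Portions start at canonical serving sizes with ±10%
uniform jitter and are refined by projected gradient descent (300
iterations, backtracking line search, early stop at relative change
1e-5) on the signed-log2 objective

`sum_n w_n * |log2(intake_n / target_n)|`

with asymmetric weights: 2.0 for under-consumed adequacy nutrients
(protein, fiber, micronutrients), 2.0 for over-consumed limit nutrients
(sodium, saturated fat, sugars), 1.0 otherwise — and 0 for limit
nutrients *below* their cap. That last weight is a deliberate deviation
from a literal reading in which every nutrient contributes: penalizing
low sodium would be scientifically perverse and contradicts the
upper-bound-only semantics used everywhere else. A cyclic
coordinate-descent polish (two sweeps of 1-D minimization) follows the
gradient loop; on 1-2-item meals the result matches an exhaustive 1 g
grid search within 2%.

Constraints then apply in a fixed order: (1) 5 g per-item minimum;
(2) per-item (400 g) and per-category (500 g) caps; (3) uniform energy
retargeting of non-capped items to the meal's energy share, tolerance
1%; (4) upper-bound-only scaling of the largest sodium / sugar /
saturated-fat contributors, never scaling up; (5) beverage gram cap
(500 g) and beverage energy at most 25% of meal energy; (6) a 900 g
total cap with rebalancing and one energy re-target, the cap winning on
conflict. Cap values are configuration defaults, not published
constants. Because stage 4 runs *after* energy retargeting, meals whose
composition cannot satisfy both energy and limits end below their energy
target: these are returned as best-effort solutions flagged infeasible
with the violated stages listed. On benchmark corpus meals roughly one
in five random archetype meals is fully feasible; the rest are honest
trade-offs (sugar-dominated snack meals, dilute single-item meals,
beverage-only meals), not solver failures.

## Metrics and evaluation

The metric suite follows the standard definitions: MER (mean
intake-to-limit ratio over the limit nutrients; we default the set to
sodium, saturated fat and added sugars, with total sugars available by
configuration), MAR (mean of `min(1, intake/RDI)` over exactly the 11
micronutrients), the AMDR composite (fraction of protein/fat/
carbohydrate energy shares inside 10-35 / 20-35 / 45-65 percent,
inclusive), Hill diversity over the meal's main-category gram
proportions (Shannon exponential at q = 1), and energy density (kcal/g).
Bootstrap CIs are percentile CIs over 1,000 resamples. The
generated-versus-real harness compares per-cluster RDI deviations:
improvement means the 95% bootstrap interval of the difference lies
below zero; the headline number is the median percent reduction in
cluster-level median deviation, reported "not applicable" when the real
median is zero. Cross-validation folds are stratified by (cluster, meal
type); strata smaller than k merge into the largest same-type stratum
with a warning.

## Substitution

Candidates for a generated meal are real meals of the same type ranked
by `0.5 * Jaccard(item sets) + 0.5 * cosine(nutrient totals)`, filtered
to comparable energy (±15%) and item count (±1), plus same-category
single-item swaps in which the removed item's grams transfer to the
added food. The hop count k is `max(|A\\B|, |B\\A|)`, so an unpaired
addition or removal counts one change. Nutrition gain is the percent
reduction in mean absolute RDI deviation; cost uses a portion-based
restaurant-style model (grams-per-portion and price-per-portion by
category, per-item caps, cross-item caps such as one billed soup bowl
per meal, a generic 150 g / $3 default, $2 overhead per meal; a grocery
per-100g dialect is available). Selection maximizes
`gain + theta * savings%` after optional budget and no-cost-increase
filters, ties preferring fewer hops then lower cost; the scalarization
is one simple reading of a nutrition-cost trade-off and is isolated
behind the policy interface. The frontier reports median gain and
savings per theta with bootstrap CIs; the operating point ("knee") is
the curve point with maximum perpendicular distance from the chord
joining the endpoints — a standard geometric knee rule chosen because no
canonical definition exists.

## Numerical conventions

All generators and stochastic routines take explicit integer seeds and
restore the caller's RNG state; per-stage pipeline seeds derive
deterministically from the global seed and the stage name, so stage
results do not depend on execution order. Ties break lexicographically
(food codes) or by declared preference order (hops, cost). Zero-energy
meals get zero ratio features with a warning; zero-variance feature
columns z-score to 0; probabilities are clipped at 1e-12 inside the BCE;
posterior log-variances are clamped to [-10, 10]. Problem sizes in the
test suite (2,000-meal benchmark, 400 held out, 40-meal portion batches,
100-meal exhaustive-search corpora) are the package's chosen desk-scale
evaluation sizes.

## Known limitations

The CVAE is trained per corpus; no transfer across corpora is attempted.
The portion optimizer's stage order resolves the energy-versus-limit
conflict in favour of limits, matching the published pipeline, but a
joint constrained solve could dominate both. The pricing model is a
single point-in-time table without geographic or temporal variation. The
synthetic corpus cannot validate claims about real survey data — only
about the algorithms.
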