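---
title: "Methods: design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dietscape estimates associations between a zip code's food environment
and socioeconomic profile on one side, and diet outcomes derived from
smartphone food journals on the other. This vignette records the model,
the parameter choices with their rationale, and the numerical and
algorithmic decisions that a reader reproducing or extending the
analysis needs to know.

## Study model

The unit of analysis is the zip code. Four **factors** are studied
(`study_factors()`): median family income, the fraction of adults with a
college degree, grocery access (the complement of the population
fraction living more than half a mile from a grocery store), and
fast-food access (the fraction of chain restaurants among nearby
restaurants). Four **outcomes** are aggregated from food logs: mean
fresh fruit-and-vegetable entries per active day (`mean_fv`), mean
fast-food entries (`mean_fastfood`), mean non-diet soda entries
(`mean_soda`), and the fraction of BMI-reporting participants with
BMI > 25 (`overweight_fraction`).

For each factor, zips are split at the median; values exactly at the cut
fall on the treated side. Directions are per-factor via
`default_direction()`: high income, high education and high grocery
access are "treated", while for fast-food access *low* is treated, so
that "treated" always denotes the nominally healthier environment. Treated zips are matched one-to-one with
replacement to control zips by genetic matching on the other three
factors, and the treatment effect on the treated is reported as the
relative difference in pair means,
$100 \cdot (\bar{y}_T - \bar{y}_C) / \bar{y}_C$, with a matched-pair
bootstrap percentile interval and a paired $t$-test cross-check.

## Classification rules

Entries are normalized (lower case, punctuation deleted, whitespace
collapsed) and matched against keyword lists shipped in
`inst/extdata/rules/`. Decisions on ambiguous points:

* **Fast food** matches on the brand field only (chain names are
  unambiguous; descriptions like "cheeseburger" at home should not
  count).
* **Soda** matches on the brand field, then excluder tokens
  (`diet`, `lite`, `light`, `zero`) in the description switch the label
  off. Excluders match whole tokens, so "delite" does not suppress.
* **Fruit & vegetables** match on brand or description (produce rarely
  has a brand), with juice/smoothie/soft-drink excluder tokens so that
  "Apple Juice" or "Cherry Coke" never counts as produce.

Inclusion keywords match as substrings ("strawberries" is caught by
"strawberr"); excluders match as whole tokens to keep them surgical.

## Aggregation

Rates are computed in two stages that mirror the clustering structure:
entries are counted within participant-day, then averaged over each
participant's *active days* (days with at least one log entry of any
kind), then averaged without weights across participants within a zip.
Filters: at least 10 active days per participant and at least 30
participants per zip, both boundaries inclusive.

## Environment covariates

Tract-level food-desert indicators are carried to zips by
population-weighted means. Fast-food access is computed per zip from a
business registry: among the (at most) 1,000 nearest restaurants within
40 km of the zip centroid (haversine distance, radius 6,371 km, stable
tie-breaking by input order), the fraction belonging to national chains.
The denominator is restaurants, not all businesses — the measure is a
property of the dining mix, not of commercial density.

## Genetic matching

Mahalanobis-style distance with a diagonal weight matrix: covariates are
standardized by their full-sample SD, and a genetic algorithm searches
the per-covariate weights $w \in (w_{\max}/10^4, w_{\max}]$ (log scale;
weights are scale-free so only ratios matter; default
$w_{\max} = 100$). Fitness is the mean absolute standardized mean
difference (SMD) across covariates after matching, with the
*control-group* SD as denominator (the treated group changes composition
under the caliper; the control pool does not). The GA uses tournament
selection of size 2, uniform crossover, log-normal multiplicative
mutation, 2 elites, and seeds the identity weights into the initial
population so the search can never end worse than unweighted matching.
Defaults of 50 individuals × 30 generations were checked against dense
grid search on small problems (the GA attains the grid optimum; see
`test-matching.R`).

The **adaptive caliper** first matches without a caliper; if any
covariate's |SMD| is 0.25 or more, it retries with a per-covariate
caliper of 2.5 SDs, shrinking by 0.1 per attempt, and raises an error
("balance unattainable") rather than return an unbalanced match once the
caliper reaches zero. The caliper applies per covariate, not to the
aggregate distance: its purpose is to forbid any single covariate from
being badly matched.

## Inference

The bootstrap resamples matched *pairs* (1,000 replicates by default),
uses the percentile 2.5/97.5 interval, and reports the two-sided sign
p-value $2 \min(\Pr^*[\hat\theta \le 0], \Pr^*[\hat\theta \ge 0])$
floored at $1/\text{reps}$. Replicates whose resampled control mean is
zero would make the ratio undefined and are redrawn. The paired
$t$-test (via `stats::t.test`) is a cross-check on the same pair
differences; with constant differences it is undefined and the result is
flagged `degenerate` instead of erroring.

## Synthetic data generator

The generator exists to validate the pipeline end to end with known
truth; its defaults encode the study conditions rather than convenient
values:

* 9.30 log entries per participant-day; mean 197 active days
  (`active_days_mean`), with a hard minimum of 10.
* Covariate medians at the study cut points: income \$70,241, college
  fraction 29.8%, grocery access 20.3%, fast-food access 5.0%.
* Majority composition 78.4% white-, 5.6% hispanic-, 3.7%
  black-majority zips; latent income is shifted down in black- and
  hispanic-majority zips, creating the confounding the matching must
  remove.
* Dependence enters through a Gaussian copula with a configurable
  correlation matrix (validated for symmetry and positive
  semidefiniteness, with offending pairs named in errors). The Spearman
  correlation of the transformed margins is $(6/\pi)\arcsin(R/2)$,
  which the tests verify.
* Outcomes are multiplicative: baseline level × one factor-indexed
  effect per treated indicator × log-normal noise
  (`noise_sd = 0.05`). Default effect sizes are stated as relative
  percentages per factor-outcome pair, with subgroup modifications
  (e.g. the income effect on F&V reverses sign in black-majority
  zips).
* Participant heterogeneity: per-participant rates are
  Gamma(shape 4) around the zip mean (relative SD 0.5), daily counts
  are Poisson, and distractor entries (soups, breads, juices,
  "Light"/"Zero" near-misses) fill the volume to the configured
  entries-per-day. The generator also returns the *realized*
  per-participant counts so tests can check exact recovery separately
  from sampling noise.

**Scope and limits.** The generator draws zips independently (no spatial
autocorrelation), renders entries from a finite vocabulary (real logs
are messier), and places zip centroids on a jittered grid spaced widely
enough that the 40 km business query of one zip never overlaps
another's. Effect heterogeneity is limited to majority-group
modifications.

## Problem sizes

The analysis scripts under `analysis/` use 400 zips × 32 participants ×
~20 active days — sizes chosen so the full workflow runs in minutes
while every estimate remains well identified. They are this package's
choices for a desk-scale demonstration, not requirements of the method;
`sim_config()` scales to the full design (≈10,000 zips) at proportional
cost.

## Performance notes

The inner loops of matching (pairwise distances and whole-population GA
fitness evaluation) are implemented in C++ (`src/nn_match.cpp`) with
cache-friendly buffered loops; a 500-zip experiment with bootstrap runs
in well under a second. All stochastic components take explicit seeds
and are exactly reproducible; the pipeline manifest records MD5 digests
of every stage file so reruns can be verified byte for byte at the
value level.
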