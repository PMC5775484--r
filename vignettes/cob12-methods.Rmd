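---
title: "Methods: search-log proxies for dietary B12 intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: search-log proxies for dietary B12 intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cob12)
```

## Overview

`cob12` implements a pipeline for infodemiology studies that treat recipe
searches as a dietary proxy: per-user food-search counts become a B12
consumption score, per-term linear probability models relate those counts
to whether a user asked about a medical term, the CoB12 statistic
summarizes how strongly a term's food coefficients track B12 content, and
a weighted rank regression relates CoB12 of drugs to their indication
breadth. Because the kind of large commercial query log such studies use
cannot be redistributed, the package ships a seeded generator that
produces structurally faithful synthetic logs with recorded ground truth;
all statistical claims in the test suite are parameter-recovery claims
about that generator.

This vignette documents the model, the generator, the main tunable
parameters, the numerical choices, and what the tests do and do not show.

## The food set

The analysis tracks 12 food types. Eleven carry published B12 contents
(mcg per 100 g): shellfish 98.9, mackerel 19, beef 6, trout 3.8, salmon
2.4, tuna 1.6, milk 0.9, turkey 0.8, egg 0.6, pork 0.4, chicken 0.3. The
twelfth, tomatoes, carries negligible B12 and is assigned content 0: it is
the negative control. We keep tomatoes in the default 12-predictor model
and in the CoB12 content vector (at 0) because the negative-control check
— that tomato coefficients stay small relative to the B12-bearing foods —
requires a fitted tomato coefficient, and because dropping a predictor
solely because its content is zero would bias the comparison it anchors.

Content figures are published per 100 g while consumption is often
discussed per serving; no serving-size table exists for these foods, so
the content vector is data (`food_reference()`, overridable) and either
convention can be injected. Unit costs per serving, used only for the
cost-weighted regional validation, are plausible retail values; only their
relative sizes matter, since the validation correlates *fractions*.

## The synthetic generator

`sim_config()` + `simulate_recipes()` / `simulate_search_log()` /
`simulate_expenditure()` / `simulate_indications()` emulate every input
the analysis needs. The causal structure is the one the analysis is meant
to detect: latent B12 intake varies across users through diet preference,
and symptom-term searching depends negatively on it.

Per user:

1. a diet preference over the 12 foods is drawn from a Dirichlet
   distribution with concentration `12 · diet_concentration ·
   ingredient_weights`. A single concentration knob controls between-user
   diet heterogeneity; 1 (default) gives strongly heterogeneous but not
   degenerate diets.
2. recipe-query counts are Poisson with mean `mean_food_searches`
   (default 2 per user for the simulated month); each query picks a food
   by preference and then a recipe containing it uniformly, and its text
   is the recipe title plus the token "recipe".
3. latent intake is defined as the *expectation of the downstream
   estimator*: `intake_u = λ · p_u' M c`, where `M[f, i]` is the
   probability that a recipe drawn for food `f` contains food `i`
   (co-ingredient smoothing computed from the corpus). The generator and
   the estimator share the content vector, which makes
   "estimator ≈ intake in expectation" an exactly testable invariant.
4. for each term, the ask indicator is Bernoulli with
   `logit P = logit(baseline_t) + effect_t · (intake_u − mean intake)`.
   The generative link is deliberately logistic while the analysis fits a
   linear probability model: the analysis should recover signs and
   orderings without knowing the true link, and the tests check exactly
   that.
5. awareness of B12 deficiency (rate `awareness_rate`) tilts the diet
   preference by `exp(shift · c_i)` with `shift ≤ 0`, shifting aware
   users toward low-B12 foods (default shift −0.05 per mcg), and emits a
   deficiency query; supplement queries follow the two conditional
   probabilities.
6. filler queries (plus one guaranteed event per otherwise-silent user)
   make the log realistic for the matcher; query templates are controlled
   so matcher precision is measurable against recorded truth.

Note on the awareness tilt direction: with a negative shift, aware users
end up with *lower* measured consumption scores, which is the observable
pattern the awareness contrast is designed to detect (deficiency-askers
having lower B12-food search activity). The generator makes no claim about
the causal direction in real populations; it encodes the association the
analysis must be able to measure.

### Default study conditions

The reference conditions are 50,000 users, a 9449-recipe corpus, 4
regions, 20 target terms with per-mcg intake effects spread evenly over
−0.08…−0.02, 20 control terms with zero effect, per-term baseline ask
rates spread geometrically over 0.8%–8% within each set, awareness rate
1%, supplement conditionals 3.83% / 0.0253% (the published proportions),
and expenditure noise sd 0.05. The population is roughly 170× smaller
than the original multi-million-user log, so rates that must yield
countable subgroups (awareness, baseline ask rates) are scaled up
accordingly; effect sizes were chosen so that the per-term log-odds shift
per intake standard deviation is of order one rather than saturating the
logistic. A spread of effect sizes (not a single value) is used so that
drug terms differ in their true association strength, which is what gives
the indication coupling below something to encode.

### Indication coupling

`simulate_indications()` draws, per drug term, an indication count
(1 + Poisson on a log scale) and a pain-indication count (binomial). With
coupling on, the indication count increases with term popularity and with
the magnitude of the term's true effect, and the pain share decreases
with that magnitude. Since more negative effects produce more negative
fitted CoB12, this encodes the sign pattern the meta-model should
recover: indication rank slope negative, pain-indication rank slope
positive. With coupling off, the table is independent noise and
meta-model p-values must be uniform — the null-calibration test.

## Query processing

All matching operates on normalized text (lowercase, punctuation
stripped, `b-12`/`b 12` mapped to `b12`).

* **Recipe matching** is transparent token containment: a query matches a
  recipe when all the recipe's title tokens occur in it; otherwise a query
  containing "recipe" and an ingredient name falls back to the best
  recipe for that ingredient. Ties prefer most title tokens matched, then
  the smallest recipe id. Precision is validated against generator truth
  (≥95% of recipe-intent events matched to the generating recipe at
  default template settings) rather than a manual audit.
* **Term matching** is exact token-boundary containment; multi-word terms
  must be contiguous. Boundaries prevent `b1`/`b12` and
  `gabapentin`/`gabapentinoid` collisions.
* **Counting convention**: a query matching a k-ingredient recipe
  increments all k food counters — the per-food-containment reading of
  counting "searches for recipes containing each food". Repeat searches
  count per event.
* **Aggregation** is order-independent and chunk-mergeable (up to the
  modal region, which needs the full stream), both tested.

## Statistical choices

* **Rank-sum tests** use the exact distribution when both groups have ≤10
  observations and no ties, else the normal approximation with tie and
  continuity corrections.
* **Relative differences** in group contrasts use the flagged group's
  mean as the base; both bases are reported. This is the convention under
  which the two published worked examples (0.5% and 8%) are simultaneously
  reproduced from their group means.
* **The per-term model** is OLS with an intercept (R² is ill-defined
  without centering), on raw counts (not per-user fractions). The
  minimum-norm solution is used, with a warning, if the design is rank
  deficient. An independent normal-equations solve is the test oracle at
  1e-8.
* **CoB12** is a Pearson correlation by default (rank correlations are
  named explicitly where intended; the unqualified "correlation" is read
  as Pearson); Spearman is available via `method`.
* **Top-k set contrast** uses the top 10 terms of each set by R²I, ties
  broken by asker count then label.
* **The meta-model** is OLS on average-rank-transformed response and
  predictors — the standard reading of rank regression consistent with
  the use of Spearman correlations elsewhere — with main effects retained
  under hierarchy alongside all interactions of the three predictors.
  Predictor ranks are centered before interactions are formed so the main
  effects are slopes at the mean rank rather than at rank zero (outside
  the data); slopes are reported on the rank scale. Weights are R²I
  normalized to mean 1, so equal weights reduce exactly to the unweighted
  fit. If the design is collinear (e.g. too few terms for the three-way
  interaction), interactions are dropped highest-order first, with a
  message. Only terms present in the indication table — drugs — enter.

## Problem sizes used in the tests

Unit and property tests run at 2,000–20,000 users. The
parameter-recovery and meta-model sign-recovery acceptance checks run 20
seeds at the full reference conditions (50,000 users, 40 terms); the
null-calibration check runs 100 seeds at 2,000 users and 20 terms, which
is sufficient because calibration concerns the null distribution, not
power. The acceptance script runs one full reference study.

## What passing tests do and do not show

The generator reproduces the *structure* of the original setting —
sparse per-user food counts, rare binary outcomes, low R² values,
popularity spread over an order of magnitude, noisy expenditure data,
coupled indication counts — but not real query text (no typos,
paraphrases or multilingual queries), no temporal structure (sessions,
bursts, seasonality), no demographic or geographic structure beyond a
region code, and no behaviour of real recipe-intent classifiers.
Parameter recovery on this generator shows the pipeline measures what it
claims to measure when the data-generating process matches its
assumptions up to the link function; it cannot show that recipe searches
track true dietary intake in the real world — that validation requires
external data, which is exactly why the regional expenditure check exists
as a stage of the pipeline.

Known limitations: the consumption score is a relative proxy (no
absolute-intake calibration, no serum-level prediction); per-term models
apply no multiple-testing correction (by design, matching the analysis
the package reproduces); CoB12 with 12 points is a coarse statistic whose
p-values are approximate under coefficient correlation; and the
shellfish content (98.9) dominates the content vector, so CoB12 is driven
substantially by the shellfish coefficient — a property inherited from
the published content table, not a package choice.
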