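# cob12

Infodemiology tooling for studying the link between dietary vitamin B12
intake and pain / neuropsychiatric complaints through web search logs.

## The problem

Profound B12 (cobalamin) deficiency causes anemia and neurological disease,
but the role of *low-to-intermediate* intake in neuropathy, chronic pain and
mood disorders is unclear, and intake is hard to measure at population
scale. Search engines offer a proxy: people search for recipes of the foods
they cook, and for the symptoms and drugs that trouble them. From a search
log one can therefore estimate, per user, a dietary B12 intake score and ask
whether users with B12-poor food searches ask more often about pain-related
medical terms.

`cob12` implements that analysis pipeline end to end, together with a
seeded synthetic search-log generator with known ground truth, so that
every stage can be validated by parameter recovery without access to any
proprietary query log.

## The model

For each user *u*, recipe searches are matched to recipes and counted per
food: `x_{u,i}` is the number of searches for recipes containing food *i*
(12 foods: shellfish, mackerel, beef, trout, salmon, tuna, milk, turkey,
egg, pork, chicken, and tomatoes as a negligible-B12 negative control).
With `c_i` the B12 content of food *i* (mcg/100 g), the consumption score
is the dot product

```
score_u = Σ_i c_i · x_{u,i}
```

For each medical term *t* (212-term target lists and dictionary-sampled
control lists are configuration), a **linear probability model** regresses
the 0/1 indicator `y_{u,t}` ("user asked about *t*") on the 12 raw counts:

```
y_{u,t} ≈ α_t + Σ_i β_{t,i} x_{u,i}
```

Its coefficient of determination is **R²I**, and

```
CoB12_t = Pearson correlation(β_{t,·}, c)
```

is the package's headline statistic: a negative CoB12 means searchers of
B12-rich foods ask about the term *less*. Finally, CoB12 of drug terms is
modeled as a function of term popularity, indication count and
pain-indication count (all average-ranked, main effects plus interactions)
by **weighted least squares with weights proportional to R²I** — the
rank-regression meta-model.

Side analyses reproduce the consumption-validation arithmetic: the
regional correlation of cost-weighted query fractions with expenditure
survey fractions, awareness-group consumption contrasts (Wilcoxon
rank-sum), and the deficiency-by-supplement 2×2 contingency.

## Worked example

```r
library(cob12)

cfg <- sim_config(seed = 42, n_users = 10000)
run <- run_study(cfg, min_askers = 50)
print(run$report)
```

Output (abridged):

```
== B12 search-pattern study report ==
config: 10000 users, 9449 recipes, 4 regions, seed 42

-- consumption contrasts --
asked_deficiency: mean 31.517 (n=102) vs 48.916 (n=9898); rel diff 55.2% (flagged base); ranksum p=0.0039

-- supplement contingency --
deficiency askers asking supplements: 3.92% (4/102); others: 0.02% (2/9898); rate ratio 194; 98.98% never asked

-- regional validation --
Pearson r=0.97 (p=4.3e-15, N=24 cells, 4 regions)

-- target vs control sets --
median R2I ratio (top 10) = 1.8 (ranksum p=4.3e-05); mean CoB12 target -0.42 vs control -0.06 (ranksum p=0.00037)

-- drug indications & meta-model --
rank regression (weights=R2I): R2=0.42 (p=0.043, N=32)
  rank_n_indications                       slope=-0.31 p=0.25
  rank_n_pain                              slope=0.55 p=0.025
```

Reading it: users who asked about B12 deficiency have visibly lower
consumption scores (the generator tilts aware users toward low-B12 foods);
deficiency askers ask about supplements two orders of magnitude more often
than others; the cost-weighted query fractions track the (synthetic)
expenditure survey almost perfectly; target terms have negative mean CoB12
while controls sit near zero; and the meta-model recovers the generator's
built-in sign pattern — more indications, lower CoB12; more pain
indications, higher CoB12.

Each stage is also available on its own (`simulate_recipes()`,
`simulate_search_log()`, `aggregate_users()`, `estimate_b12()`,
`fit_term_models()`, `fit_meta_model()`, …) and every function takes and
returns plain tibbles, so custom pipelines compose with the pipe.
`plot_term_association()`, `plot_regional_validation()` and
`autoplot()` on the meta-model fit give the standard figures;
`tidy()`/`glance()` work on the meta-model fit.

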