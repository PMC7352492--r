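# nutrinet

Systems-nutrology analysis of adolescent food-frequency questionnaire (FFQ)
cohorts in R.

Adolescents frequently misjudge their own weight. Comparing BMI-for-age
status with self-perceived weight yields a three-level label — the
*divergence between measured and perceived weight* (DMPW): **Agreed**,
**Underestimated**, or **Overestimated**. `nutrinet` implements a complete
pipeline for asking how weight misperception relates to diet: not only *how
much* of each food group adolescents eat, but whether their consumption of
different food groups rises and falls *together* — and whether
misperception is marked by inverse (negative) consumption relationships.

The package is aimed at nutritional epidemiologists working with
semi-quantitative FFQ data on school-based cohorts, and at methodologists
who want a tested, synthetic-data-driven reference implementation of
bootstrap-stabilized food-consumption networks.

## What it computes

1. **FFQ processing** — frequency categories (`never/rare`, `1-3/month`,
   `1/week`, `2-4/week`, `>=4/week`) × portion sizes → daily grams per
   item, aggregated to 14 food groups.
2. **Anthropometry & DMPW** — BMI with uniform-mass correction,
   BMI-for-age percentile bands (underweight < 3rd, normal \[3, 85),
   overweight \[85, 97), obese ≥ 97th), and the ordinal DMPW rule.
3. **Dietary patterns** — ecology-style *abundance of consumption*
   (each group's share of total intake), Ward hierarchical clustering
   (Euclidean distance) into k patterns, per-pattern profiles with one-way
   ANOVA (Holm-adjusted), and pattern × covariate composition tables.
4. **Modelling** — multinomial logistic regression of pattern membership
   on DMPW (adjusted for sex and status, configurable baseline pattern),
   with the cluster-sampling design effect `Deff = 1 + (m̄ − 1)·ICC`.
5. **Networks** — per-DMPW-group Spearman correlation matrices of
   food-group intakes, stabilized by bootstrap: an edge is kept only if it
   has adjusted p < 0.05 **and** |rho| > 0.5 with a consistent sign in at
   least 50% of 100 bootstrap replicates. Network density is
   `L / (N(N − 1)/2)`; densities are compared between DMPW groups with
   Kruskal–Wallis + Dunn (Holm).
6. **Synthetic cohorts** — a generator that plants known dietary-pattern
   centroids and signed rank-correlation structure through a log-normal
   Gaussian copula (Spearman targets calibrated via
   `rho_P = 2 sin(π rho_S / 6)`), records the ground truth, and lets every
   stage be tested for parameter recovery.

## Worked example

```r
library(nutrinet)

cfg <- run_config(generator = network_recovery_config(n_subjects = 900),
                  network_B = 100, seed = 7)
run <- run_pipeline(cfg)
run
#> <nutrinet pipeline run>  n = 900  seed = 7
#> DMPW distribution:
#>             dmpw   n      pct
#> 1         Agreed 278 30.88889
#> 2 Underestimated 329 36.55556
#> 3  Overestimated 293 32.55556
#> ...
#> network Agreed         L = 13  density = 0.1429  negative = 0
#> network Underestimated L = 10  density = 0.1099  negative = 0
#> network Overestimated  L =  7  density = 0.0769  negative = 4

tidy(run$networks$Overestimated)
#> # A tibble: 7 × 5
#>   group1              group2     sign     median_rho persistence
#> 1 processed_meat      oils       positive      0.538        0.64
#> 2 milk_dairy          meat       positive      0.659        1
#> 3 processed_meat      roots      negative     -0.583        0.97
#> 4 oils                roots      negative     -0.715        1
#> 5 sweetened_beverages vegetables negative     -0.618        1
#> 6 rice_cereals        fruits     positive      0.640        1
#> 7 roots               coffee_tea negative     -0.569        0.9

glance(run$density_comparison)
#> # A tibble: 1 × 4
#>   test           statistic    df  p.value
#> 1 Kruskal-Wallis      275.     2 1.68e-60
```

Read: in this synthetic benchmark the Overestimated group carries planted
inverse consumption relationships (roots vs oils, processed meat and
coffee/tea; vegetables vs sweetened beverages). The pipeline retains
exactly those negative edges, only in that group, and its bootstrap
network density is the lowest of the three DMPW groups (Kruskal–Wallis on
per-replicate densities, p ≪ 0.001) — the qualitative signature the method
is designed to detect.

Real data enter through `run_config(cohort_path = ..., responses_path =
..., group_map_path = ...)` as delimited text; `?aggregate_food_groups`,
`?add_anthropometry` and `?read_group_map` document the schemas.

## Vignette

`vignettes/systems-nutrology.Rmd` describes the model and its assumptions,
the synthetic-data design (what it emulates and what it deliberately does
not), all tunable thresholds, and known limitations.
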