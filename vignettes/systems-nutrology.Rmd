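---
title: "Systems nutrology: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems nutrology: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrinet)
```

`nutrinet` analyses adolescent FFQ cohorts along two complementary axes:
*composition* (which food groups dominate a subject's diet, summarised as
dietary patterns) and *co-regulation* (which food groups rise and fall
together across subjects, summarised as signed correlation networks). This
vignette is the package's own account of the underlying models, the
decisions taken where the design was genuinely open, and what the tests do
and do not establish.

## 1. From FFQ responses to daily grams

A semi-quantitative FFQ records, per food item, a frequency category and a
portion size (g, with mL treated as g at unit density — the instrument
records volumes without densities). Daily intake is
`portion × occasions/day`. The occasions/day multipliers for the interval
categories are not canonical across published FFQs; the package defaults
to interval midpoints:

| category    | occasions/day | rationale                       |
|-------------|---------------|---------------------------------|
| never/rare  | 0             | definition                      |
| 1–3/month   | 2 / 30.44     | midpoint; month = 365.25/12 d   |
| 1/week      | 1 / 7         | definition                      |
| 2–4/week    | 3 / 7         | midpoint                        |
| ≥4/week     | 5.5 / 7       | open-ended top category; a 4–7 midpoint convention, overridable |

All multipliers are overridable (`ffq_frequency_factors()`), because the
top-category convention in particular is a choice, not a fact. Items are
summed into 14 food groups through a user-supplied item→group map; the
package's `default_group_map()` is a synthetic stand-in (two items per
group), not a reproduction of any validated instrument.

## 2. Anthropometric status and DMPW

BMI uses a uniform-mass correction (default 100 g subtracted from measured
weight, for subjects weighed in school uniform). Status comes from
BMI-for-age percentile bands closed on the left: underweight [0, 3),
normal [3, 85), overweight [85, 97), obese [97, 100]. Growth references
are *inputs*: the package consumes a precomputed percentile column, or an
LMS table (sex, age in months, L, M, S) via `lms_percentile()`, and
bundles no reference data.

DMPW compares measured status with self-perception on a shared 3-level
ordinal scale. Perception collapses {very thin, thin}→thin and {fat, very
fat}→fat. Measured status maps underweight→0, normal→1, and
overweight→2 **and** obese→2: because the perception scale tops out at
"fat", merging overweight and obese is the only reading under which the
rule classifies all 12 (status × perception) cells with no gaps. Agreed
means equal levels; Underestimated, perceived below measured;
Overestimated, perceived above measured. Two structural impossibilities
follow: no overestimation among the overweight/obese, no underestimation
among the underweight. The (obese, fat) cell classifies as Agreed under
the ordinal rule — consistent with obese subjects appearing only in the
Agreed group in observed cohorts, though worded nowhere as an explicit
rule; we adopt it as the ordinal rule's consequence.

## 3. Abundance and dietary patterns

*Abundance of consumption* divides each subject's food-group grams by
their total intake — the ecology-style relative abundance of the diet.
Rows sum to 1 and the transform is invariant to a subject's overall
intake scale; a zero-total subject is an error (identified by id), never a
NaN row. Patterns are found by agglomerative Ward clustering
(`hclust(method = "ward.D2")`, the algorithm that implements Ward's
minimum-variance criterion on Euclidean distances) over raw abundance
rows, cut at `k` (default 4). Abundance fractions already live on a
common [0, 1] scale, so no further standardization is applied by default;
`scale_groups = TRUE` offers per-group z-scoring for users who want
variance-equalized clustering. A column dendrogram over food groups is
computed for display only — assignments depend solely on the row
clustering. `k` is a default, not a constant; silhouette-style scans are
left to the user since no within-package criterion chose 4.

Pattern profiles report per-pattern × group mean ± SD of abundance and a
per-group one-way ANOVA across patterns, Holm-adjusted over the 14 tests
(`aov` + `p.adjust`). Abundance is stored as fractions and displayed as
percentages; published tables of this quantity sometimes print values
incompatible with row-normalized percentages (column entries above 100),
so no attempt is made to match any specific printed scaling — the package
implements the definition.

## 4. The multinomial model and the design effect

Pattern membership is modelled by maximum-likelihood multinomial logit
(`nnet::multinom`) with DMPW as exposure (reference: Agreed) adjusted for
sex and status, reporting exponentiated coefficients with Wald 95% CIs.
The baseline outcome defaults to the pattern with the flattest profile
(no predominant food group) — in practice the uniformly-low pattern —
and is configurable. Separation or non-convergence raises an explicit
diagnostic rather than silent output.

School-based cohorts are sampled by conglomerate (schools, then classes),
so observations are not independent. The package reports the standard
cluster-sampling design effect `Deff = 1 + (m̄ − 1)·ICC`, with the ICC
estimated by one-way ANOVA variance components (clamped at ≥ 0). For the
categorical pattern outcome the ICC is the prevalence-weighted mean of
per-level indicator ICCs — an outcome-level summary, chosen because no
per-coefficient formula is canonical. Deff > 3 is flagged as
sampling-influenced. The exact survey-weighting scheme used alongside such
models in published analyses is generally unrecoverable; `nutrinet`
implements cluster-size-proportional weights plus the Deff diagnostic and
documents that choice rather than claiming equivalence.

Power for the fold-change design is estimated by Monte Carlo: log-normal
intakes with common CV (default 0.8), one group's median shifted by the
fold change, compared by Kruskal–Wallis. The distributional assumptions
are the package's own. At 50 subjects/group, 2-fold shift and alpha 1%,
simulated power exceeds 90% (the suite asserts this).

## 5. Bootstrap-stabilized signed networks

For each DMPW group, the G × G Spearman matrix of food-group intakes
(tie-corrected, two-sided p from the t approximation) is bootstrapped
B = 100 times (resamples with replacement at original n). An edge between
two food groups enters the stable network only if, **within a replicate**,
it simultaneously has adjusted p < 0.05 and |rho| > 0.5 — and does so,
with a consistent sign, in at least 50% of replicates. Choices worth
stating:

- **Adjusted p.** The significance criterion is Holm-adjusted within each
  replicate's G(G−1)/2 tests by default (`adjust_p = FALSE` disables it).
  With |rho| > 0.5 as a co-criterion the adjustment is rarely binding at
  n ≥ 300, but it governs behaviour at small n.
- **Sign-consistent persistence.** A replicate where the pair qualifies
  with the opposite sign does not count towards persistence; mixing signs
  would make the reported edge sign meaningless. Edge sign is the majority
  sign; edge rho is the median over qualifying replicates of that sign.
- **Strict boundaries.** |rho| = 0.5 and p = alpha are excluded; a
  persistence of exactly 50/100 is retained ("minimum of 50%").
- **Everything within replicates.** Criteria are applied per replicate,
  not to a full-sample matrix gated by bootstrap stability — the only
  reading under which "persisted in 50% of the bootstraps" is
  well-defined.
- **Degenerate pairs.** A constant column (possible in small resamples)
  yields rho 0, p 1, and a degeneracy flag rather than NaN.

Density is `L/(N(N−1)/2)`. For between-group comparison, criteria (i)–(ii)
are applied within each replicate to give B densities per group — the only
within-group distribution the procedure generates — compared by
Kruskal–Wallis with hand-computed Dunn z-tests (tie-corrected, Holm over
pairs; no Dunn implementation ships with base R). Node analysis reports
per-group degree (retained-correlation counts).

## 6. The synthetic-cohort generator

The generator emulates a ~1,500-adolescent school cohort and records the
planted truth so every stage can be recovery-tested.

**Marginals.** Defaults: 57.1% female; DMPW (0.683, 0.197, 0.120); status
(0.081 underweight, 0.772 normal, 0.088 overweight, 0.059 obese). Status
is drawn restricted to the DMPW label's feasible set (an obese
overestimator is structurally impossible; configurations forcing one are
rejected at config time, not silently reassigned). The BMI-for-age
percentile is drawn uniformly within the assigned status band, and the
perceived response is obtained by inverting the DMPW rule — so planted
labels re-classify identically, for 100% of subjects, by construction.

**Intakes.** Per DMPW group, a Gaussian copula on the log scale: latent
normals with Pearson correlation `2 sin(π rho_S / 6)` — the exact
normal-scores calibration, so planted Spearman values are targets, not
approximations — pushed through log-normal marginals whose location is
the subject's pattern centroid (mean log grams/day, seeded from realistic
adolescent food-group medians) and whose scale is `noise_scale` (default
0.5). Target matrices must be symmetric, unit-diagonal and PSD; a
near-PSD violation is repaired by `Matrix::nearPD` projection, and
repairs beyond `psd_tolerance` (0.05) are errors. Because rank
correlations survive monotone transforms, the within-pattern Spearman
matrix equals the target in expectation.

**An explicit caveat:** the *pooled* Spearman matrix of a DMPW group
equals the target only when its subjects share one marginal location.
With widely separated pattern centroids, between-pattern variation
dilutes within-pattern correlation (a planted −0.7 can pool to ≈ 0).
This is a property of mixtures, not a bug; the two benchmark
configurations therefore isolate one axis each:

- `pattern_recovery_config()` — centroid contrasts at 2.5× on the log
  scale, noise 0.3: four well-separated abundance blobs. Ward k = 4
  recovers planted labels with ARI ≥ 0.9 (typically 0.94–0.99 at
  n = 600), and all 14 per-group ANOVAs are significant after Holm.
  The separation/noise pair was fixed once, at design time, as the
  regime a clustering benchmark is meant to probe.
- `network_recovery_config()` — equal DMPW groups (n = 300/group), a
  single pattern centroid, default noise: the pooled group Spearman then
  matches the planted structure (max deviation < 0.1 at n ≈ 2000).
  Planted structure: dense all-positive blocks in Agreed (13 edges) and
  Underestimated (10 edges); a sparser Overestimated structure whose
  negative star (roots against oils, processed meat, coffee/tea;
  roots–oils = −0.7) comes from a one-factor model so the matrix is PSD
  *by construction*, plus a vegetables–sweetened-beverages inverse pair —
  8 edges, 4 negative. The factor model's side effect (an
  oils–processed-meat rho of ≈ 0.54) is part of the planted edge list.

**Clusters.** Subjects sit in 50 school-class conglomerates; pattern
membership is drawn from cluster-level mixture weights (Dirichlet around
the global weights with concentration `(1 − icc)/icc`). The default
ICC 0.004 was chosen once so that `1 + (1496/50 − 1)·0.004 ≈ 1.12`, a
low design effect typical of class-level sampling of behavioural
outcomes; it is a package default, not an empirical estimate.

**FFQ responses.** The generator inverts the FFQ module: group intake is
split evenly over mapped items, each item's implied occasions/day
(target / reference portion, default 100 g) is snapped to the nearest
grid multiplier, and the portion is set so `category × portion`
reproduces the target exactly. The only loss is quantization to
never/rare for targets below half the monthly rate of the reference
portion — at most `ref × (2/30.44)/2 ≈ 3.3 g/day` per item — the bound
the round-trip tests assert for 100% of subjects.

**What the generator does not emulate:** seasonal and day-to-day intake
variation, item-level reporting error, the content of any validated
97-item instrument, differential misreporting by weight status, and any
sex–DMPW association (sex is drawn independently, so synthetic sex × DMPW
tables are null). Passing recovery tests therefore demonstrates
correctness of the estimators under the stated generative model — not
robustness to FFQ measurement error or informative missingness in real
cohorts.

## 7. Problem sizes used by the suite

The test suite and acceptance script run at deliberately moderate sizes
chosen to make the targeted effects decisively detectable while keeping a
full run in the minutes range: cohorts of 120–1,496 subjects; copula
fidelity at n ≈ 2,000 per group; network recovery at 300/group with
B = 100 over 20 seeds; 200 null multinomial fits at n = 1,500; power at
500 Monte-Carlo replicates. These sizes are the package's own choices and
are easily raised in user code.

## 8. Known limitations

- Dunn z-tests use the normal approximation; at very small replicate
  counts exact methods would differ.
- The multinomial model's weights are design-motivated but are not a full
  complex-survey variance estimator (no linearization/replicate weights);
  CIs at strong within-cluster correlation will be anticonservative.
- mL-as-g ignores density differences across beverages.
- The stable-network procedure controls family-wise error within
  replicates, but the persistence filter's joint error rate across the
  91 pairs has no closed form; the identity-structure null test
  (empirically zero retained edges at n = 300) is the operative control.
- Ward clustering on compositional data uses plain Euclidean geometry;
  log-ratio geometries (Aitchison) are a defensible alternative the
  package does not implement.
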