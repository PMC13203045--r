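---
title: "Modeling cognition from longitudinal gut metagenomes: methods and design notes"
author: "gutcog maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cognition from longitudinal gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## 1. The modeling problem

Longitudinal microbiome–cognition cohorts produce three linked data streams:
compositional feature tables (species, MetaCyc pathways, KEGG orthologs) per
stool sample, per-visit clinical covariates, and per-visit cognitive
assessments. Two statistical facts dominate the design:

* **Compositionality.** Metagenomic relative abundances are proportions
  closed to 1 per sample. Every reader in `gutcog` enforces closure (sum
  within 1e-6 of 1 after renormalization) and rejects zero-total samples at
  read time.
* **Repeated measures.** Samples from the same subject are correlated.
  Every model in the package carries a subject-level random intercept, and
  every resampling scheme (train/test splits, importance folds) moves whole
  subjects, never individual samples.

## 2. Cohort preparation

**Classification.** Subjects are labeled once, from the baseline visit:
a clinician-reported dementia diagnosis gives `AD`; otherwise a CDR below 1
together with normal daily functioning and an ADAS-Cog-13 word-list delayed
recall score of at least 4 gives `MCI`; everyone else is `HC`. "Normal daily
functioning" is taken as a boolean metadata field; the package makes no
attempt to derive it from instruments.

**Composite scores.** The memory composite is the sum of the ADAS-Cog-13
word recall, word recognition, orientation, remembering-word-recognition
instructions, and delayed recall scores. The executive-function composite
sums maze time, maze mistakes, and the two NIH Toolbox scores (dimensional
card sort, pattern comparison). The Toolbox scores are higher-is-better, so
they are sign-flipped before summation; the composite is therefore uniformly
higher-is-worse. Each composite is z-standardized *within visit index across
all subjects assessed at that visit* — not within cognitive group, which
would change the scale of every downstream model. Two open choices were
settled as follows and are switchable:

* **SD convention**: the sample (n−1) standard deviation (`ddof = 1`).
* **Visit key**: the ordinal visit index, not calendar windows; visit dates
  in these cohorts drift by days, not by visit periods.
* Visits where the z-score is undefined (singleton visit group, zero SD)
  raise an error by default; pipelines that sweep a whole cohort use
  `on_undefined = "drop"` because the last scheduled visit of a long cohort
  routinely has a single attendee.

**Diversity and the linear mixed models.** Alpha diversity is the inverse
Simpson index `1 / sum(p^2)`. The two study formulas — diversity on sex,
age, education, antibiotic use, days since enrollment and cognitive status,
and cognitive score on time and status, each with `(1 | subject)` — are fit
by REML via `lme4::lmer` behind a single `fit_random_intercept_lmm()`
contract with Wald z-tests. Time is days since enrollment, untransformed;
cognitive status is treatment-coded with HC as reference.

## 3. The mixed-effects random forest

The model is `y_ij = f(x_ij) + b_i + e_ij` with a forest for `f`, and the
fit alternates:

1. de-bias the outcome, `y* = y − b̂`;
2. refit the bagged regression forest on `(X, y*)`;
3. closed-form intercept update
   `b̂_i = n_i σ²_b / (n_i σ²_b + σ²_e) · mean(residual_i)`;
4. moment/EM variance updates for the intercept-only design
   (`σ²_e ← (1/n) Σ_i [ε̂'ε̂ + σ²_e(n_i − σ²_e tr V_i⁻¹)]`,
   `σ²_b ← (1/m) Σ_i [b̂_i² + σ²_b − σ²_b (1'V_i⁻¹1) σ²_b]`);
5. track the generalized log-likelihood (GLL) and stop when its relative
   change falls below `gll_tolerance`.

**Forest.** No random-forest package is assumed: `src/forest.cpp` implements
bagged CART regression trees (variance-reduction splits, `mtry = p/3`,
minimum leaf 5), out-of-bag predictions, and per-tree out-of-bag permutation
importance. All randomness flows through R's RNG, so a single `set.seed`
fixes the entire model.

**Fixed-part estimate during EM.** Out-of-bag predictions by default
(`use_oob_for_fixed_part`): in-bag forest predictions absorb part of the
residual and drive `σ̂²_e` toward collapse.

**Convergence and the iteration cap.** The GLL contains an `m · log σ²_b`
term. In degenerate data with no cluster effect, `σ̂²_b` decays geometrically
toward zero and this term keeps the GLL moving, so the relative-change rule
never fires and the iteration cap alone decides how completely the variance
collapses. The default cap is therefore 50 (not the more conventional 30):
at 30 iterations the collapse is visibly incomplete
(`σ̂²_b/σ̂²_e ≈ 0.06` on 100 clusters × 5 with no true cluster effect,
vs ≈ 0.04 at 50; the acceptance suite checks `< 0.05`).

**Prediction is personalized.** `predict()` adds `b̂_i` for clusters seen in
training and only `f̂(x)` for unseen clusters. With the
leave-one-sample-per-subject split, every test sample comes from a training
subject, so reported test correlations measure how well a subject's
accumulated history extends to a held-out visit — not out-of-sample
generalization to new subjects. This is deliberate and matches the
personalized-prediction reading of the analysis; interpret accordingly.

## 4. Boruta

Per iteration a shuffled shadow copy of every still-undecided feature is
appended (padded to a floor of five shadows, as in the reference
implementations, so the max-shadow bar does not collapse late in the run), a
forest is fitted, and a feature scores a *hit* when its importance Z-score
(out-of-bag permutation importance, mean over trees divided by its standard
error) exceeds the best shadow. Decisions use two-sided binomial tests of
the hit count against p = 0.5 with a Bonferroni correction over the initial
feature count; undecided features at `max_runs` stay *tentative* and are
**not** selected (no rough fix) — the conservative policy. Clinical
covariates compete with microbiome features on equal terms
(no `always_keep` exemption), and Boruta runs on pooled samples, ignoring
subject clustering — a known leakage-adjacent simplification implied by the
pipeline order (selection precedes the mixed model).

A calibration note: in pure-noise designs the features with the largest
chance correlations (at n = 200, the maximum |r| over 50 noise features is
about 0.19) can genuinely beat the shadow bar in well over half the
iterations and end up confirmed. This is inherent to the all-relevant
formulation — those features *are* informative about that particular
realization of the outcome — and shows up in the acceptance suite as a mean
false-confirmation count hovering around one per 50-feature noise dataset.

## 5. Permutation importance and its null

`permutation_importance()` is the cross-validated ("held-out") variant: the
fixed-part forest is refitted on all but one cluster-grouped fold (outcome
de-biased by the model's intercepts) and the importance of a feature is the
increase in held-out squared error when its column is permuted within the
fold, averaged over repeats and folds. Two details matter for calibration,
both measured during development and encoded in the defaults:

* **Refit, don't re-evaluate.** Evaluating the final model on its own
  training data biases the importance of every feature the forest touches
  upward and starves the mirrored null of non-positive values.
* **Few, large folds** (default 3). Permuting within a small fold couples
  the permuted column with the fold's own empirical distribution; the
  resulting right-tail inflation of null importances scales roughly with the
  reciprocal of fold size (all-noise p ≤ 0.05 fraction ≈ 0.10 with 5 folds
  vs ≈ 0.07 with 3 folds at n = 200).
* The cluster intercepts are excluded from the held-out evaluation: fold
  intercepts depend on fold outcomes and couple the error with the forest,
  again inflating every importance. The intercept is feature-independent,
  so it cancels from the error increase.

**Significance.** The default null is the *mirrored* null: non-positive
importances reflected about zero, with p the unsmoothed empirical upper
tail. Unsmoothed is deliberate: with add-one smoothing the smallest
attainable BH q-value is about (null size)/(feature count) ≈ 1, and the
reporting rule "FDR equivalent < 0.1" could never fire. The route requires
at least 10 non-positive importances and errors otherwise, demanding the
**Altmann fallback**: refit the model on permuted outcomes `n_perm` times
and use the resulting importances as the null (with add-one smoothing, as is
standard there). The per-species covariate screen, whose models have ~15
covariates, uses the Altmann route with draws pooled across covariates —
pooling trades a comparable-scales assumption for p-value granularity that
per-feature nulls cannot reach at affordable permutation counts.

**Annotation.** Spearman ρ per feature (average ranks for ties; two-sided p
from the t-approximation, chosen over exact small-n methods for uniformity),
BH q across the report's tested feature set, and the two reporting flags:
strong = |ρ| ≥ 0.4, significant = p ≤ 0.05 and q < 0.1. All three thresholds
are arguments.

## 6. The pipelines

**Cognitive pipeline** (`run_cognitive_pipeline`): per seed — a
leave-one-sample-per-subject split (single-sample subjects stay entirely in
training rather than being discarded), Boruta on the training samples over
prevalence-filtered features (present in ≥ 10% of the group's samples)
plus the 8 minimal covariates (sex, age, antibiotics, hospitalization,
malnutrition, frailty, polypharmacy, education; medications never enter this
pipeline, to avoid outcome leakage), a MERF on the training samples, and
Pearson (with Spearman alongside — the "correlation" convention is
unstated upstream, Pearson is the primary) between actual and predicted on
the held-out samples. Boruta selections are per-seed; the final model uses
their union on all samples. Seeds for every stage derive arithmetically from
one master seed, so reports are byte-reproducible.

**Covariate screen** (`covariate_screen`): one MERF per species predicting
its relative abundance from the full covariate set *including* per-class
medication indicators, permutation importance with the pooled Altmann null,
BH within each species model at q < 0.05, then a covariate frequency ranking
(share of models where significant) and a demographic/clinical/medication
category breakdown.

**Cross-outcome comparison** (`compare_rankings`): the union of top-k
features across reports with each feature's rank and ρ per outcome.

## 7. The synthetic cohort: what it emulates, and what it does not

Defaults reproduce the structure the analysis assumes: 158/40/25 HC/MCI/AD
subjects; visits every 90 days with a truncated negative-binomial count per
subject (mean 3.8, SD 2.4, minimum 1); group-wise covariate distributions
(age 70.2 ± 7.46 / 75.1 ± 7.22 / 73.9 ± 5.75; female 69/52.5/48%;
polypharmacy 27.2/40/68%; antibiotics 17.7/22.5/8%; hospital exposure
8.2/10/4%; CFS 2.07/2.54/3.52; MIS 1.21/1.28/1.68; ADAS-Cog-13
9.01 ± 4.42 / 21.0 ± 12.8 / 32.3 ± 20.1). Education is not tabulated in the
source cohort; 14 ± 3 years for all groups is assumed. About 5% of visits
lack a stool sample (cognitive-only visits; these still contribute to visit
z-score means, since standardization is over assessments, not samples).

**Feature tables** use independent log-normal latents per feature with a
subject-level latent offset (SD `subject_tau`, the source of within-subject
autocorrelation), per-feature presence probabilities drawn from
`prevalence_range` at the subject level, then closure. This is the simplest
mechanism giving realistic mean–variance shape and subject autocorrelation;
it deliberately ignores phylogenetic correlation, diet/medication causal
structure, and sequencing noise — a green recovery test says the pipeline
works under the stated statistical structure, not that it is robust to
everything real data does.

**Outcome.** `latent = Σ planted effects + b_i + N(0, σ_e)`, with planted
effects acting on the z-scored arcsine-square-root abundance (bounded
leverage; `linear`, `threshold`, and `interaction` shapes). The latent is
mapped *monotonically* onto the ADAS-Cog-13 scale through a per-group
moment-matched truncated normal on [0, 85]: a hard clip of a normal with the
AD group's moments would cut ~5% of its mass at zero and shrink the group SD
by about 5%, breaking the generator's stated moment-convergence property;
quantile mapping preserves ranks (hence planted signal) and the configured
group moments under the bounded support. The total is split into itemized
subtests by fixed, documented proportions (word recall .18, word recognition
.16, orientation .10, remembering instructions .06, delayed recall .14, maze
time .12, maze mistakes .06 — the remainder stands for the non-itemized
tasks) plus noise; baseline delayed-recall values are nudged across the
MCI threshold (≥ 4) or below it (HC) so classification exactly recovers the
generating groups. Toolbox scores are generated higher-is-better.

The paper-scale effect size of microbiome→cognition associations is unknown;
the default planted `effect_size = 1` (one latent-SD per feature-SD) makes
recovery achievable but not trivial with 5 planted features against
σ_b = σ_e = 1, and is config-exposed.

`null_cohort()` permutes the outcome block (total, subtests, Toolbox,
jointly) across all visits with a derived seed: identical tables, broken
feature–outcome link, the pipeline's negative control.

## 8. Numerical conventions

* All seeds derive from one master seed via fixed integer arithmetic
  (`derive_seed`), keeping every derived seed under 2³¹.
* Variance iterates are floored at 1e-8; the residual floor warns.
* BH is implemented directly (step-up with a cumulative minimum) and is
  checked in the tests against an O(m²) literal-definition oracle;
  enrichment uses `phyper` checked against exhaustive enumeration.
* MetaPhlAn percent-vs-proportion dialects are auto-detected from per-sample
  totals; `UNMAPPED`/`UNINTEGRATED` are excluded before closure by a
  configurable list. Whether pathway tables should be re-closed at all is
  not settled upstream; proportion closure is this package's convention.
* Config files are YAML (or JSON); TOML is not supported.

## 9. Known limitations

* Personalized prediction leaks subject history by construction; do not read
  test correlations as new-subject generalization.
* Boruta ignores clustering during selection (pipeline-order simplification)
  and, in noise-only designs, will occasionally confirm the most
  chance-correlated feature (Section 4).
* The mirrored importance null is approximate; its calibration was measured
  (and its parameters chosen) under iid noise features, and degrades when
  most features are informative or fold sizes are small.
* Stability of selected features across cohort perturbations is not
  evaluated (no stability selection).
* No batch-effect correction is included.
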