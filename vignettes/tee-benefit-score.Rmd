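---
title: "Methods: deriving and validating a TEE benefit score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and validating a TEE benefit score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teescore)
```

# The estimation problem

Intraoperative transesophageal echocardiography (TEE) during isolated CABG
is a non-randomized exposure: sicker patients and better-resourced
hospitals use it more. The package's target is the *conditional* average
treatment effect (CATE) of TEE on operative mortality — the change in
death probability TEE causes for a patient with a given clinical
phenotype — and a practical discretization of it, the TEE score, that a
hospital could use to triage limited TEE capacity.

The analysis emulates a randomized trial in two stages, always separately
within hospital-volume strata (low < 100, medium 100–250, high > 250
annual CABG cases), because institutional capability both confounds TEE
use and plausibly modifies its benefit:

1. **Derivation.** A random 25% training subset is matched 1:1
   (TEE vs no TEE). On the matched sample we fit one logistic model of
   mortality on treatment, six prespecified modifiers (ejection fraction,
   CHF, creatinine, >50% left-main stenosis, ≥3 diseased coronaries,
   inotrope use within 48 h) and all treatment-by-modifier interactions.
   The fitted CATE is cut at its training quintiles into scores 1–5
   (1 = most predicted benefit).
2. **Validation.** The reserved 75% is scored with the *frozen* cutpoints,
   matched again within stratum, and TEE vs no TEE mortality is compared
   per score subgroup with paired methods. Honest validation rests on the
   train/test split: the subgroups being tested were defined without
   touching the validation outcomes.

## Assumptions

* No unmeasured confounding given the matching covariates (probed, not
  guaranteed, by the E-value and negative-control analyses).
* Logistic outcome model with linear, untransformed continuous modifiers;
  a single interaction model rather than separate per-arm models, so that
  one coherent CATE function exists. This is a modelling choice, not a
  consequence of the design; a per-arm alternative would differ mainly
  when arm-specific nuisance effects are strong.
* Matching within volume stratum removes hospital-level confounding to
  the extent volume proxies it.

# Matching as an optimization problem

Pairs must emulate randomization, so the matcher enforces, in strict
priority order:

1. **Pair count** — as many 1:1 pairs as the constraints allow;
2. **Near-fine balance** — minimal total absolute discrepancy between the
   treated and matched-control category counts of the fine-balance
   variables (targets are the counts among all treated in the block);
3. **Total Mahalanobis distance** over the matching covariates.

Admissible edges require exact agreement on the blocking variables and a
logit-propensity difference within the caliper. The problem is solved
exactly as an integer minimum-cost network flow
(source → treated → controls → fine-balance categories → sink) by
successive shortest paths with node potentials (Dijkstra). Each
augmentation adds one cheapest pair, so the final flow is simultaneously
maximum-cardinality and minimum-cost at that cardinality; the test suite
checks it against exhaustive enumeration on small instances.

Numerical choices:

* Distances enter the solver as `round(1e4 * d)` — integer costs with
  four decimals of resolution.
* One unit of fine-balance overflow costs more than the largest possible
  total distance (`sum(costs) + 1`), which realizes the lexicographic
  ordering inside a single cost function.
* The covariance behind the Mahalanobis metric is estimated on the pooled
  sample within stratum and ridge-regularized by `1e-8·I` so collinear
  covariates cannot make it singular.
* **Sparsification** (`max_candidates`, default 30): each treated record
  is connected only to its 30 caliper-admissible controls nearest on the
  logit propensity scale. This bounds solver work on large strata; with
  `Inf` the solver is exactly optimal, and the optimality tests run in
  that mode.
* Ties between equally good matchings are resolved deterministically by
  processing records in identifier order; the *objective value* is
  order-invariant (tested under row permutation), the particular pair set
  need not be.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `caliper` | 0.2 | SD of logit propensity | standard practice for propensity calipers |
| `exact` | `surgery_year` (+ `tee_score` in stage 2) | – | secular trends; score subgroups must compare like with like |
| `fine_balance` | `admit_source` | – | categorical margin worth balancing without pairwise equality |
| `max_candidates` | 30 | controls/treated | solver work vs optimality trade-off |
| `train_fraction` | 0.25 | – | derivation/validation split |
| `conf_level` | 0.95 | – | two-sided, α = 0.05 |

## Arm equalization before matching

When one arm greatly outnumbers the other (TEE prevalence ≈ 62%), optimal
matching keeps every scarce-arm record and *selects* which majority-arm
records enter pairs. That selection minimizes distance, so it
systematically drops hard-to-match records and can skew matched-group
margins even on covariates the propensity model considers irrelevant. The
pipeline therefore draws a random (seeded) subset of the majority arm of
the minority arm's size before matching. Selection into the matched set is
then independent of covariates, at the price of discarding excess
majority-arm records a 1:1 design could never pair anyway. Both behaviours
are available: `match_pairs()` itself never subsamples.

# Paired inference

With pairs in hand the analysis is classical matched-pairs inference on a
2×2 of concordance counts (a, b, c, d):

* RD = 100(b − c)/n percentage points, identical to the difference of the
  arms' marginal rates; Wald CI with SE = 100·√((b+c) − (b−c)²/n)/n and a
  Wald z test. The paired Wald interval was chosen because it uses only
  the discordance structure and is exact-arithmetic-checkable from
  published margins.
* Exact McNemar test: p = min(1, 2·P(Bin(b+c, ½) ≤ min(b, c))); with no
  discordant pairs the test is vacuous and reported as 1 with a warning.
* Conditional OR = b/c, with exact limits from Clopper–Pearson bounds on
  θ = b/(b+c) mapped through θ/(1−θ); c = 0 yields an infinite OR and
  upper limit, reported as such rather than truncated.
* Benjamini–Hochberg correction is applied within one stratum across its
  six rows (pooled + scores 1–5), separately for the RD-test and OR-test
  p-value families — the narrowest family a reader of a per-stratum table
  would assume. Wider families (all strata jointly) would only relabel the
  same ranking.

Degenerate subgroups (no pairs, or no discordant pairs) yield flagged rows
with missing estimates instead of errors, so a small stratum cannot abort
a report.

## Sensitivity analyses

The E-value of a risk ratio RR (after OR→RR conversion) is
RR* + √(RR*(RR*−1)) with RR* = max(RR, 1/RR). Defaults:

* **Rare-outcome conversion** (RR = OR), since operative mortality is
  ≈ 2%; the square-root conversion is available for common outcomes (and
  would be more appropriate for the negative control, whose incidence is
  ≈ 25%).
* The headline E-value of a subgroup is the **CI-based** one — the E-value
  of the interval limit nearest the null, exactly 1 when the interval
  spans the null. Point-estimate E-values are reported alongside.

The negative-control outcome (new-onset postoperative atrial fibrillation)
has a zero treatment effect *by construction* in the generator; pooled
rows whose OR interval excludes 1 are flagged as evidence of residual
bias. Supplemental outcomes (coronary reintervention, stroke, chest
re-exploration) run through the identical machinery.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis must
survive, not any real registry's joint distribution:

* three volume strata with hospital-level volumes patients inherit;
* confounded assignment: a logistic propensity model sharing standardized
  covariates (age, EF, creatinine, CHF, inotropes, coronary anatomy, PROM,
  admission route) with the outcome models; intercepts are calibrated
  numerically (`uniroot`) so realized prevalence (default 0.618), untreated
  mortality (default 0.025) and negative-control incidence (default 0.25)
  hit their targets;
* heterogeneous benefit: stratum-specific treatment log-odds
  `main + γᵀ·modifiers`, by default concentrated on the
  left-main/three-vessel/inotrope phenotype in low and medium strata
  (γ = −0.7, −0.5, −1.0) and null in the high stratum; the ground-truth
  per-record probability difference is exported as `true_cate`;
* sparse completely-at-random missingness (default 5·10⁻⁴) on covariates
  only, handled by median/mode single imputation, plus optional injection
  of records violating each registry exclusion rule.

**Scale calibration.** The package's default study size is 50,000
surgeries per stratum — roughly one twentieth of the motivating registry —
chosen so the full two-stage pipeline runs in well under a minute on one
CPU. At that size the stage-1 matched sample contains only a few hundred
deaths, so the default interaction strengths are set larger than the
modest subgroup contrasts a full-size registry would need: they are the
smallest round values at which the interaction estimates' sampling error
(SE ≈ 0.3 on the common binary modifiers at this event count) leaves the
phenotype ranking reliably recoverable. Consequences worth knowing: the
pooled ORs in low/medium strata are stronger than a full-size analysis
would show, and the rare inotrope modifier (1.2% prevalence) is often
quasi-separated in the stage-1 fit — its interaction then takes an extreme
value, aliased or near-aliased terms are set to zero with a warning, and
ranking is driven by the two common modifiers, which is the intended
behaviour of a score, not a failure mode.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: realistic joint covariate distributions,
informative missingness, hospital-level practice effects beyond volume,
clinician-level confounding, or any PROM model internals (PROM is drawn as
a covariate, never derived).

## Quintile mechanics and edge cases

* Cutpoints are the 20/40/60/80 empirical percentiles (type-7 linear
  interpolation) of the *matched training* CATEs — matched records, not
  all training records, because the CATE model's estimand is defined on
  the matched population.
* Bins are half-open with the top bin closed; values tying a cutpoint go
  to the lower (more-benefit) score, a deterministic and
  benefit-conservative rule.
* All-equal training CATEs give every record score 1 with a warning;
  fewer than five training values is an error.

## Determinism and seeds

One master seed expands to stage seeds via a label hash
(`derive_seed(seed, label)`, label ∈ generate/split/thin1-⟨stratum⟩/…,
kept within 32-bit range), so stages are reproducible in isolation and
the whole pipeline is bit-identical under a fixed seed: identical report
CSVs byte for byte, which the tests assert.

# Known limitations

* 1:1 matching only — no 1:k, full matching, or matching with
  replacement; excess majority-arm records are discarded by design.
* With `max_candidates` finite the matcher is only optimal on the
  sparsified network; pathological instances could lose feasible pairs.
* The paired Wald RD interval is first-order; for very small subgroups the
  exact McNemar p and the exact OR limits are the trustworthy quantities.
* The CATE model is parametric and prespecified; no machine-learned CATE
  estimators or cross-fitting.
* E-values quantify robustness, not bias detection; the negative control
  detects only confounders it shares with the primary outcome.

# Problem sizes used by the shipped experiments

The analysis drivers and the heavy validation tests use 50,000 surgeries
per stratum (the package's reference study size); unit tests use 2,000 to
6,000; the negative-control coverage study uses 200 replicates of 3,000
surgeries each. These sizes are the package's own accuracy/turnaround
choices and are stated here so readers can scale them up for sharper
comparisons.
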