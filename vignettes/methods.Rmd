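---
title: "Methods: a clinical prediction rule and triage algorithm for cranial giant cell arteritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a clinical prediction rule and triage algorithm for cranial giant cell arteritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcatriage)
```

## The clinical problem

Cranial giant cell arteritis (cGCA) is a vasculitis of the temporal and
other cranial arteries in older adults. First-line imaging is ultrasound
of the temporal arteries; with high-resolution compression sonography
(hrTCS) the summed near- and far-wall thickness is measured and the test
is called positive at **≥ 0.7 mm** (inclusive). Like every imaging
test, its predictive values depend on the pre-test probability in the
population it is applied to: in an unselected referral stream most
positives in low-risk patients are false. `gcatriage` implements an
explicit, point-based pre-test stratification and the triage algorithm
built on it, together with the statistical machinery needed to derive
and evaluate such a rule.

## The prediction rule

Four clinical items are scored and summed:

| item | points |
|---|---|
| age > 70 years | 1 |
| new-onset persistent headache | 1 |
| jaw claudication | 1 |
| AION, unilateral | 1 |
| AION, bilateral | 2 |

Anterior ischemic optic neuropathy (AION) enters through its laterality;
bilateral disease implies permanent visual impairment and carries double
weight. A patient with **≤ 1 point has low clinical probability**;
≥ 2 points is non-low. Age exactly 70 scores 0 points: the model
variable is strictly "age > 70", and we do not expose the boundary as an
option. The items as tabulated sum to at most 5, although the published
score range is 0–6 (see *The six-point discrepancy* below).

The stepwise algorithm then routes each patient:

* **non-low probability** → hrTCS, irrespective of C-reactive
  protein (CRP);
* **low probability and CRP ≥ 2.5 mg/dL** (inclusive) → hrTCS;
* **low probability and CRP < 2.5 mg/dL** → cGCA rejected without
  imaging.

On the imaging routes the final classification is "suspected" exactly
when the sonographic test is positive. The algorithm is a deterministic
triage classifier; it emits no probabilities. A low-probability patient
with a missing CRP is an error, not a silent assumption: the route is
genuinely undecidable. A non-low patient does not need a CRP at all.

```{r}
pt <- data.frame(patient_id = "A", cohort = "clinic", age = 75,
                 new_onset_headache = 1, jaw_claudication = 1,
                 aion = "none", crp = 0.8, wall_thickness = 0.9,
                 hrtcs_result = NA, final_diagnosis = NA)
classify_patient(pt)
```

## Tunable parameters

All thresholds live in one YAML configuration (see
`system.file("extdata", "default-config.yaml", package = "gcatriage")`);
there are no hidden constants in the code paths.

* `crp_cutoff`, 2.5 mg/dL, inclusive. Some published prose uses "> 2.5";
  we treat the explicit "≥ 2.5 mg/dL" statement of the algorithm
  definition as authoritative and read the other phrasing as loose.
* `wall_cutoff`, 0.7 mm, inclusive, the summed-wall positivity cut-off
  of the sonographic probe (published operating point roughly 85%
  sensitivity, 95% specificity).
* `category_threshold`, 2 points.
* The five item weights, non-negative integers.

## The six-point discrepancy

The published score table prints a 0–6 range and the pooled
accuracy table contains a score-6 stratum of five patients, yet the
printed items sum to at most 5. The package implements the items exactly
as printed (maximum 5) and exposes the weights, so a six-point variant
is one configuration away: `six_point_weights()` sets bilateral AION to
3 points. The pooled fixture uses that variant to realise the score-5
and score-6 strata; the low/non-low split is unaffected because
bilateral AION reaches the category threshold under either weighting,
and the scores 0–3 strata contain no bilateral-AION patients, so
all category-level and score-2/3 statistics are identical under both
weightings.

## Deterministic fixtures

No patient-level data accompany the published study, so the package
ships two fully synthetic, deterministic rosters (87 and 114 records)
that satisfy every recomputable published count: category splits (53/34
and 60/54), CRP-branch assignments (25 and 4 imaged low-probability
patients), rejection counts (28 and 56, none with cGCA), the stratified
sonography cell counts, and — pooled and scored with the six-point
variant — the per-score stratum sizes 39/74/39/17/14/13/5 and case
counts 1/2/11/10/14/13/5. `build_fixture()` constructs the roster from a
cell-count table and *validates it on construction* against the
transcribed constraints (`fixture_constraints()`, `validate_fixture()`);
an inconsistency is a hard error. Everything not pinned by a published
count is a documented free choice (the provenance JSON next to each CSV
lists them): which items realise each score, the per-cohort score
histograms inside the published category totals, and representative
continuous values (age 75/62, CRP 5.0/1.0 mg/dL, wall 0.9/0.5 mm) kept
constant so the fixtures are byte-stable.

Two published numbers admit no integer realisation and are deliberately
**not** reproduced: the low-probability NPV of 98.4% (the unique tables
give 50/51 = 98.0% in the derivation stratum and 64/65 = 98.5% in the
pooled score-1 row), and the abstract's 32.8% no-imaging fraction
(the flow counts give 28/87 = 32.2%). The 2×2 reconstruction
solver reports such rows as inconsistent, and the test suite asserts
that it does.

## Reconstructing 2x2 tables from printed summaries

`reconstruct_table(n, cases, ppv, npv)` enumerates all integer tables
with the given margin and keeps those whose recomputed predictive values
round — **half-up, one decimal, percentage scale** (`round_half_up()`,
matching how clinical tables are typeset; R's own `round()` rounds half
to even) — to the printed pair. A printed "/" (undefined value) is
interpreted as a zero denominator. The solver returns the unique
solution, flags multiple solutions as ambiguous, and errors on rows no
table can produce. Uniqueness is a property of each row, not assumed.

## Diagnostic accuracy and ROC

Sensitivity, specificity, PPV, NPV and prevalence are simple cell
ratios; a zero denominator yields an explicitly undefined metric, never
a silent 0. Wilson score intervals are attached to every defined
proportion — an extension beyond the published tables, which print no
intervals for predictive values.

The AUC uses the midrank Mann–Whitney formulation: the probability
that a random case outscores a random control, ties credited one half,
computed from ranks in O(n log n). This equals the trapezoidal area
over the operating points at all distinct thresholds; the test suite
verifies the identity against a brute-force O(n²) pairwise oracle
and against an independent implementation (pROC). The published AUCs of
the derivation study (0.96 and 0.92) and the winning model's AIC (48.6)
require the unpublished patient-level data and are therefore documented
as non-reproducible; the machinery is validated by property-based
checks instead.

## Model derivation

`fit_logistic()` is a from-scratch iteratively reweighted least squares
(IRLS) maximiser of the binomial likelihood. Numerical choices, all
fixed: convergence when the largest absolute coefficient change falls
below 1e-8, an iteration cap of 100, coefficients started at zero, and
separation flagged (not fatal) when any coefficient passes 15 in
absolute value — at that point the likelihood is still improving but the
MLE does not exist, which is exactly what happens when a score item
perfectly splits a small cohort. Wald intervals
(coefficient ± z·SE on the log-odds scale) are used because
the source analysis names no interval method; profile-likelihood
intervals are a documented alternative we did not implement. No Firth
penalisation, by design. `select_model()` ranks candidate item sets by
AIC = 2k − 2·logL, ties broken by parsimony then input order.
Univariate screening wraps base R: Pearson χ² without
continuity correction (the convention was unstated; no Yates) and the
Mann–Whitney U with normal approximation and tie correction.

AION enters the design as two mutually exclusive dummies (unilateral,
bilateral) against a "none" reference, matching the two separate
log-odds-ratios of the published model.

## The cohort simulator

`simulate_cohort()` draws the diagnosis Bernoulli(prevalence), then the
clinical items *conditionally independently given the diagnosis*, CRP
from a per-group log-normal, wall thickness from a per-group
zero-truncated normal, and age from a per-group normal truncated to the
correct side of 70 to agree with the drawn indicator. Defaults are
calibrated once to the derivation cohort's published margins:
prevalence 26/87; headache 80.8%/18.0%; jaw claudication 61.5%/3.3%;
unilateral AION 50.0%/9.8% and bilateral 11.5%/1.6%; age normals 73.2
(9.2) and 66.1 (11.2) years, giving age > 70 probabilities of 0.636 and
0.364; CRP log-normals moment-matched to 5.2 (5.3) and 4.2 (5.6) mg/dL;
wall thickness N(1.0, 0.3) vs N(0.45, 0.15) mm, placing the 0.7 mm
cut-off near the probe's published 85%/95% operating point.

Conditional independence has a useful consequence (the naive-Bayes /
logistic identity): the implied true disease log-odds are *exactly*
linear in the five indicators, with closed-form coefficients
(`spec_true_coefficients()`). That gives the parameter-recovery and
interval-coverage simulations a ground truth that owes nothing to the
fitting code. The suite checks 95% Wald coverage between 90% and 99%
over 200 replicates at n = 2000, AIC recovery of the generating model
against a noise-augmented rival in a majority of 100 replicates at
n = 1000, and calibration of all per-group frequencies within 3
standard errors at n = 100{,}000 (problem sizes chosen as the smallest
at which the asymptotic checks are stable).

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: correlation between items given the
diagnosis (real headache and age are not independent), measurement
error in wall thickness, missingness mechanisms (CRP was missing for 5
of 92 derivation patients; the simulator never generates missing CRP),
referral selection (the validation cohort was preselected for permanent
visual loss), and extracranial disease. On that last point, two
published patients with isolated extracranial GCA would have been
rejected unimaged by the algorithm; this is a documented limitation of
the rule itself, not a code path.

## Degenerate inputs and tie-breaks

Empty cohorts yield all-zero flow summaries. Single-class outcomes,
rank-deficient designs and length mismatches are explicit errors with
stable `[CODE]` prefixes. AIC ties go to the smaller model, then input
order. Score ties in the ROC are handled by midranks. Equal-weight
fixture choices (e.g. which score-1 non-case gets the age item vs the
headache item) alternate deterministically so the rosters are
byte-stable across builds.
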