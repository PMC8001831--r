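# gcatriage

Pre-test probability stratification for suspected **cranial giant cell
arteritis (cGCA)**, for clinical epidemiologists and vascular-medicine
researchers who want to evaluate — or re-derive — point-based triage of
temporal artery ultrasound.

## The rule and the algorithm

A four-item clinical prediction score:

| item | points |
|---|---|
| age > 70 years | 1 |
| new-onset persistent headache | 1 |
| jaw claudication | 1 |
| anterior ischemic optic neuropathy (AION), unilateral | 1 |
| AION, bilateral | 2 |

Patients with ≤ 1 point have *low* clinical probability. The stepwise
algorithm refers all non-low patients for high-resolution temporal
artery compression sonography (hrTCS, positive at summed wall thickness
≥ 0.7 mm), refers low-probability patients only when C-reactive protein
(CRP) is ≥ 2.5 mg/dL, and rejects the diagnosis without imaging
otherwise. Rejection is safe in both packaged cohorts: no rejected
patient carries a final cGCA diagnosis.

Beyond scoring and routing, the package provides:

* stratified diagnostic accuracy (sensitivity/specificity/PPV/NPV with
  Wilson intervals, undefined metrics flagged rather than zeroed) and a
  midrank Mann–Whitney ROC/AUC;
* `reconstruct_table()`, an exhaustive integer 2×2 solver that recovers
  stratum cell counts from printed predictive-value pairs — and reports
  printed rows that no integer table can produce;
* model-derivation machinery: hand-written IRLS logistic regression
  with Wald intervals, AIC ranking of candidate item sets, and
  univariate χ²/Mann–Whitney screening;
* two deterministic synthetic cohort fixtures (n = 87 and n = 114)
  validated at build time against every recomputable published count,
  plus a seeded stochastic cohort simulator (`simulate_cohort()`)
  calibrated to the derivation cohort's margins.

## Worked example

```r
library(gcatriage)

derivation <- build_fixture("derivation")   # or read_patients("your.csv")
run_cohort(derivation)
#> Cohort flow (n = 87)
#>   low probability:      53 (60.9%)
#>   non-low probability:  34 (39.1%)
#>   rejected, no imaging: 28   low+high CRP imaged: 25   non-low imaged: 34
#>   route x final diagnosis:
#>                    route  n n_cgca n_alternative
#>        reject_no_imaging 28      0            28
#>  hrtcs_low_prob_high_crp 25      2            23
#>       hrtcs_non_low_prob 34     24            10
```

60.9% of the cohort is low probability; 28 patients (32.2%) are spared
imaging and none of them has cGCA; of the 34 non-low patients, 24 are
true cases. Stratified test performance:

```r
evaluate_cohort(build_fixture("validation"))
#> ...
#>   low        PPV  11.1%  NPV 100.0%
#>   non_low    PPV  85.3%  NPV 100.0%
```

In the low-probability stratum only 1 of 9 sonography positives is a
true case (PPV 11.1%) — the enrichment delivered by the score raises
the PPV to 85.3% in the non-low stratum. Reconstructing a printed
stratum from its summary alone:

```r
reconstruct_table(n = 17, cases = 10, ppv_pct = 75, npv_pct = 80)
#>           diagnosis
#> test       cGCA alternative
#>   positive    9           3
#>   negative    1           4
```

A command-line wrapper with subcommands `score`, `classify`,
`evaluate`, `derive`, `simulate`, `reconstruct` and `fixtures` ships at
`system.file("cli", "gcatriage.R", package = "gcatriage")`.

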