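{
  "fixture": "derivation_cohort.csv",
  "synthetic": true,
  "description": "Constraint-satisfying synthetic roster (n = 87, 26 cGCA). Not real patients. Reproduces the published derivation-cohort counts: 53 low / 34 non-low probability at score threshold 2; 28 rejected without imaging (CRP < 2.5 mg/dL, none with cGCA); 25 low-probability patients imaged because CRP >= 2.5 mg/dL (2 cGCA, one sonography-negative, no false positives, 23 true negatives); non-low stratum 21 TP / 2 FP / 3 FN / 8 TN.",
  "free_choices": [
    "Per-cohort score histogram within the published category totals: 20 patients at score 0 (8 imaged via the CRP branch, 12 rejected) and 33 at score 1; the published per-cohort histograms were figure-only and were not digitized.",
    "Clinical item combinations realising each score: score-1 patients are new-onset headache only (cases) or alternate headache / age>70 (non-cases); score-2 cases headache+jaw claudication, non-cases age+headache; score-3 cases age+headache+jaw, non-cases age+headache+unilateral AION; score 4 age+headache+jaw+unilateral AION; scores 5-6 include bilateral AION.",
    "False-positive and false-negative placement within the non-low stratum: 1 FP + 2 FN at score 2, 1 FP + 1 FN at score 3, consistent with the statement that all false positives had scores 2-3.",
    "Single low-probability false positive placed at score 1 in the rejection branch so the low-stratum sonography cells are TP 1 / FP 1 / FN 1 / TN 50 (PPV 50%; NPV 50/51 = 98.0%, the published 98.4% admits no integer table).",
    "Representative continuous values only: age 75 when the age item is present else 62; CRP 1.0 mg/dL below / 5.0 mg/dL above the 2.5 cut-off; wall thickness 0.9 mm for sonography-positive and 0.5 mm for sonography-negative patients."
  ]
}
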