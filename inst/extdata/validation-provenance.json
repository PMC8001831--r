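{
  "fixture": "validation_cohort.csv",
  "synthetic": true,
  "description": "Constraint-satisfying synthetic roster (n = 114, 30 cGCA). Not real patients. Reproduces the published validation-cohort counts: 60 low / 54 non-low probability at score threshold 2; 56 rejected without imaging (none with cGCA); 4 low-probability patients imaged because CRP >= 2.5 mg/dL (1 sonography-positive cGCA, 3 sonography-negative alternatives); non-low stratum 29 TP / 5 FP / 0 FN / 20 TN; low-stratum sonography cells TP 1 / FP 8 / TN 51 (PPV 1/9 = 11.1%, NPV 100%).",
  "free_choices": [
    "Per-cohort score histogram within the published category totals: 19 patients at score 0 and 41 at score 1.",
    "The single low-probability case is placed at score 0 and the eight low-probability false positives split 1 at score 0 / 7 at score 1, so that pooling with the derivation roster reproduces the published pooled per-score accuracy rows.",
    "Non-low false positives split 3 at score 2 / 2 at score 3; true negatives 19 at score 2 / 1 at score 3.",
    "Clinical item combinations and representative continuous values as in derivation-provenance.json."
  ]
}
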