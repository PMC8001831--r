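{
  "fixture": "concatenation of derivation_cohort.csv and validation_cohort.csv (n = 201, 56 cGCA)",
  "synthetic": true,
  "description": "Scored with the six-point weight variant (bilateral AION = 3 points), the pooled roster reproduces the published per-score accuracy table: stratum sizes 39/74/39/17/14/13/5 for scores 0-6, case counts 1/2/11/10/14/13/5, and every consistent PPV/NPV pair (score-0 50/100, score-2 69.2/92.3, score-3 75/80, scores 4-6 PPV 100 with no negative tests).",
  "free_choices": [
    "The printed score items sum to at most 5, yet the published range is 0-6 with a populated score-6 stratum; the fixture realises scores 5 and 6 with a configured variant weighting bilateral AION at 3 points. The low/non-low category split is identical under either weighting because bilateral AION always reaches the category threshold. This forces 18 bilateral-AION patients (13 at score 5, 5 at score 6), more than the 13 tabulated in the published marginals; the stratum constraints dominate the marginals.",
    "The published score-1 NPV of 98.4% admits no integer 2x2 table (the unique PPV-consistent table gives 64/65 = 98.5%); the fixture realises the PPV-consistent table and the discrepancy is surfaced, not fitted."
  ]
}
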