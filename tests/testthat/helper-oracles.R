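# Independent oracles used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# AUC as the probability that a random case outscores a random control,
# ties credited one half: brute-force O(n^2) over all case-control pairs.
auc_pairwise_oracle <- function(scores, truths) {
  cases <- scores[truths]
  controls <- scores[!truths]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Pearson chi-squared for a 2x2 table, direct formula (no correction).
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# One patient record row with sensible defaults, overridable by name.
patient <- function(age = 60, new_onset_headache = 0L, jaw_claudication = 0L,
                    aion = "none", crp = 1.0, wall_thickness = 0.5,
                    hrtcs_result = NA_character_,
                    final_diagnosis = "alternative",
                    patient_id = "P1", cohort = "derivation") {
  data.frame(patient_id = patient_id, cohort = cohort, age = age,
             new_onset_headache = new_onset_headache,
             jaw_claudication = jaw_claudication, aion = aion, crp = crp,
             wall_thickness = wall_thickness, hrtcs_result = hrtcs_result,
             final_diagnosis = final_diagnosis, stringsAsFactors = FALSE)
}

# Binary design matrix with intercept from 2x2 cell counts
# (n11 = x1 y1, n10 = x1 y0, n01 = x0 y1, n00 = x0 y0).
design_from_2x2 <- function(n11, n10, n01, n00) {
  x <- c(rep(1, n11 + n10), rep(0, n01 + n00))
  y <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  list(x = cbind("(Intercept)" = 1, slope = x), y = y)
}
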