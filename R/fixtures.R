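#' Six-point variant of the score weights
#'
#' The published score table prints a 0-6 range and the pooled
#' per-score accuracy table contains a score-6 stratum, yet the printed
#' items sum to at most 5.  The pooled fixture therefore realises the
#' score-6 stratum with a configured variant in which bilateral AION
#' scores 3 points; the low/non-low category split is unaffected because
#' bilateral AION reaches the category threshold under either weighting.
#'
#' @return A [gca_weights()] object with `aion_bilateral = 3`.
#' @export
six_point_weights <- function() gca_weights(aion_bilateral = 3L)

# Stratum cell tables: one row per (score, route, cell) group.
# Cells name the sonography x final-diagnosis status: TP/FP = hrTCS
# positive with/without cGCA, FN/TN = hrTCS negative with/without cGCA.
# Scores are on the six-point fixture scale (bilateral AION = 3).
fixture_cells <- function(cohort) {
  derivation <- data.frame(
    score = c(0, 0, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 5, 6),
    route = c("reject", "low_imaged",
              "low_imaged", "low_imaged", "low_imaged", "reject", "reject",
              "nonlow", "nonlow", "nonlow", "nonlow",
              "nonlow", "nonlow", "nonlow", "nonlow",
              "nonlow", "nonlow", "nonlow"),
    cell = c("TN", "TN",
             "TP", "FN", "TN", "FP", "TN",
             "TP", "FN", "FP", "TN",
             "TP", "FN", "FP", "TN",
             "TP", "TP", "TP"),
    n = c(12, 8,
          1, 1, 15, 1, 15,
          4, 2, 1, 5,
          4, 1, 1, 3,
          6, 5, 2))
  validation <- data.frame(
    score = c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 5, 6),
    route = c("low_imaged", "reject", "reject",
              "low_imaged", "reject", "reject",
              "nonlow", "nonlow", "nonlow",
              "nonlow", "nonlow", "nonlow",
              "nonlow", "nonlow", "nonlow"),
    cell = c("TP", "FP", "TN",
             "TN", "FP", "TN",
             "TP", "FP", "TN",
             "TP", "FP", "TN",
             "TP", "TP", "TP"),
    n = c(1, 1, 17,
          3, 7, 31,
          5, 3, 19,
          5, 2, 1,
          8, 8, 3))
  switch(cohort, derivation = derivation, validation = validation,
         gca_stop("INVALID_VALUE", paste("unknown cohort:", cohort)))
}

# Clinical item combination realising a given six-point-scale score.
# Returns c(age, headache, jaw, aion).  `case` switches between the
# combination used for cGCA patients and for alternative diagnoses;
# `alt_variant` alternates score-1 non-case items for marginal variety.
fixture_items <- function(score, case, alt_variant = FALSE) {
  if (score == 0) return(list(age = 62, headache = 0L, jaw = 0L, aion = "none"))
  if (score == 1) {
    if (!case && alt_variant)
      return(list(age = 75, headache = 0L, jaw = 0L, aion = "none"))
    return(list(age = 62, headache = 1L, jaw = 0L, aion = "none"))
  }
  if (score == 2) {
    if (case) return(list(age = 62, headache = 1L, jaw = 1L, aion = "none"))
    return(list(age = 75, headache = 1L, jaw = 0L, aion = "none"))
  }
  if (score == 3) {
    if (case) return(list(age = 75, headache = 1L, jaw = 1L, aion = "none"))
    return(list(age = 75, headache = 1L, jaw = 0L, aion = "unilateral"))
  }
  if (score == 4) return(list(age = 75, headache = 1L, jaw = 1L,
                              aion = "unilateral"))
  if (score == 5) return(list(age = 75, headache = 1L, jaw = 0L,
                              aion = "bilateral"))
  if (score == 6) return(list(age = 75, headache = 1L, jaw = 1L,
                              aion = "bilateral"))
  gca_stop("INVALID_VALUE", paste("no item combination for score", score))
}

#' Build a deterministic cohort fixture
#'
#' Constructs, without any randomness, a patient roster that reproduces
#' every recomputable published count for the requested cohort: the
#' low/non-low category split, the CRP-branch assignment, the
#' no-imaging count (with zero cGCA diagnoses among rejected patients)
#' and the stratified sonography true/false positive/negative counts.
#' The pooled roster is the concatenation of the two cohorts and, scored
#' with [six_point_weights()], reproduces the per-score stratum sizes and
#' case counts of the pooled accuracy table.  The roster is validated
#' against [fixture_constraints()] on construction; a failure is a hard
#' error.
#'
#' Free choices not pinned by the published counts (which clinical items
#' realise each score, the per-cohort score histograms within the
#' published category totals, representative CRP / wall-thickness values)
#' are documented in the provenance file shipped next to the fixture
#' (`inst/extdata/*-provenance.json`).
#'
#' @param cohort `"derivation"` (n = 87), `"validation"` (n = 114) or
#'   `"pooled"` (n = 201).
#' @return Data frame of patient records.
#' @export
build_fixture <- function(cohort = c("derivation", "validation", "pooled")) {
  cohort <- match.arg(cohort)
  if (cohort == "pooled") {
    records <- rbind(build_fixture("derivation"), build_fixture("validation"))
  } else {
    cells <- fixture_cells(cohort)
    prefix <- if (cohort == "derivation") "D" else "V"
    rows <- vector("list", sum(cells$n))
    k <- 0L
    for (i in seq_len(nrow(cells))) {
      score <- cells$score[i]
      route <- cells$route[i]
      cell <- cells$cell[i]
      case <- cell %in% c("TP", "FN")
      pos <- cell %in% c("TP", "FP")
      for (j in seq_len(cells$n[i])) {
        k <- k + 1L
        it <- fixture_items(score, case, alt_variant = j %% 2 == 0)
        crp <- if (route == "reject") 1.0
        else if (route == "low_imaged") 5.0
        else if (case) 5.0 else 1.0
        wall <- if (pos) 0.9 else 0.5
        rows[[k]] <- data.frame(
          patient_id = "", cohort = cohort, age = it$age,
          new_onset_headache = it$headache, jaw_claudication = it$jaw,
          aion = it$aion, crp = crp, wall_thickness = wall,
          hrtcs_result = if (pos) "positive" else "negative",
          final_diagnosis = if (case) "cGCA" else "alternative",
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    records$patient_id <- sprintf("%s%03d", prefix, seq_len(nrow(records)))
  }
  report <- validate_fixture(records, fixture_constraints(cohort),
                             fixture_config(cohort))
  if (!all(report$pass)) {
    gca_stop("FIXTURE_INCONSISTENT", paste(
      "fixture fails published constraint(s):",
      paste(report$label[!report$pass], collapse = "; ")))
  }
  validate_patients(records)
  records
}

# Scoring configuration under which a cohort's constraints are stated:
# Table-2 weights for the per-cohort flows, the six-point variant for the
# pooled per-score table.
fixture_config <- function(cohort) {
  if (cohort == "pooled") gca_config(weights = six_point_weights())
  else gca_config()
}

#' Published constraints for the shipped fixtures
#'
#' Transcription of the recomputable published counts as declarative
#' constraints usable with [validate_fixture()]: category and route
#' totals with their final-diagnosis breakdown for each cohort, and the
#' per-score stratum sizes, case counts and sonography-positive counts of
#' the pooled accuracy table (stated on the six-point fixture scale).
#'
#' @param cohort `"derivation"`, `"validation"` or `"pooled"`.
#' @return List of constraints; each is a list with `label`, `expected`
#'   and a `where` filter (fields among `score`, `category`, `route`,
#'   `hrtcs_pos`, `diagnosis`).
#' @export
fixture_constraints <- function(cohort = c("derivation", "validation",
                                           "pooled")) {
  cohort <- match.arg(cohort)
  cn <- function(label, expected, ...) {
    list(label = label, expected = as.integer(expected), where = list(...))
  }
  if (cohort == "derivation") {
    return(list(
      cn("n total", 87),
      cn("cGCA diagnoses", 26, diagnosis = "cGCA"),
      cn("low probability", 53, category = "low"),
      cn("non-low probability", 34, category = "non_low"),
      cn("rejected without imaging", 28, route = "reject_no_imaging"),
      cn("rejected with cGCA (safety)", 0, route = "reject_no_imaging",
         diagnosis = "cGCA"),
      cn("low probability imaged (CRP branch)", 25,
         route = "hrtcs_low_prob_high_crp"),
      cn("low imaged with cGCA", 2, route = "hrtcs_low_prob_high_crp",
         diagnosis = "cGCA"),
      cn("low imaged cGCA, sonography negative", 1,
         route = "hrtcs_low_prob_high_crp", diagnosis = "cGCA",
         hrtcs_pos = FALSE),
      cn("low imaged false positives", 0,
         route = "hrtcs_low_prob_high_crp", diagnosis = "alternative",
         hrtcs_pos = TRUE),
      cn("non-low with cGCA", 24, category = "non_low", diagnosis = "cGCA"),
      cn("non-low true positives", 21, category = "non_low",
         diagnosis = "cGCA", hrtcs_pos = TRUE),
      cn("non-low false positives", 2, category = "non_low",
         diagnosis = "alternative", hrtcs_pos = TRUE),
      cn("low stratum sonography-positive cGCA", 1, category = "low",
         diagnosis = "cGCA", hrtcs_pos = TRUE),
      cn("low stratum false positives", 1, category = "low",
         diagnosis = "alternative", hrtcs_pos = TRUE)))
  }
  if (cohort == "validation") {
    return(list(
      cn("n total", 114),
      cn("cGCA diagnoses", 30, diagnosis = "cGCA"),
      cn("low probability", 60, category = "low"),
      cn("non-low probability", 54, category = "non_low"),
      cn("rejected without imaging", 56, route = "reject_no_imaging"),
      cn("rejected with cGCA (safety)", 0, route = "reject_no_imaging",
         diagnosis = "cGCA"),
      cn("low probability imaged (CRP branch)", 4,
         route = "hrtcs_low_prob_high_crp"),
      cn("low imaged cGCA, sonography positive", 1,
         route = "hrtcs_low_prob_high_crp", diagnosis = "cGCA",
         hrtcs_pos = TRUE),
      cn("low imaged sonography-negative alternatives", 3,
         route = "hrtcs_low_prob_high_crp", diagnosis = "alternative",
         hrtcs_pos = FALSE),
      cn("non-low with cGCA", 29, category = "non_low", diagnosis = "cGCA"),
      cn("non-low true positives (all cases)", 29, category = "non_low",
         diagnosis = "cGCA", hrtcs_pos = TRUE),
      cn("non-low false positives", 5, category = "non_low",
         diagnosis = "alternative", hrtcs_pos = TRUE),
      cn("low stratum sonography positives", 9, category = "low",
         hrtcs_pos = TRUE),
      cn("low stratum missed cases", 0, category = "low",
         diagnosis = "cGCA", hrtcs_pos = FALSE)))
  }
  # pooled: per-score rows (six-point scale)
  sizes <- c(39, 74, 39, 17, 14, 13, 5)
  cases <- c(1, 2, 11, 10, 14, 13, 5)
  tps <- c(1, 1, 9, 9, 14, 13, 5)
  pos <- c(2, 9, 13, 12, 14, 13, 5)
  out <- list(cn("n total", 201),
              cn("cGCA diagnoses", 56, diagnosis = "cGCA"))
  for (s in 0:6) {
    out <- c(out, list(
      cn(sprintf("score %d stratum size", s), sizes[s + 1], score = s),
      cn(sprintf("score %d cGCA cases", s), cases[s + 1], score = s,
         diagnosis = "cGCA"),
      cn(sprintf("score %d true positives", s), tps[s + 1], score = s,
         diagnosis = "cGCA", hrtcs_pos = TRUE),
      cn(sprintf("score %d sonography positives", s), pos[s + 1], score = s,
         hrtcs_pos = TRUE)))
  }
  out
}

#' Check a patient roster against declarative constraints
#'
#' Scores and routes the records under `config`, derives each patient's
#' sonographic status, and counts the records matching each constraint's
#' filter.
#'
#' @param records Data frame of patient records.
#' @param constraints List of constraints as in [fixture_constraints()].
#' @param config A [gca_config()] giving the scoring weights and cut-offs
#'   under which the constraints are stated.
#' @return Data frame report: `label`, `expected`, `observed`, `pass`.
#' @export
validate_fixture <- function(records, constraints, config = gca_config()) {
  if (length(constraints) == 0) {
    return(data.frame(label = character(), expected = integer(),
                      observed = integer(), pass = logical()))
  }
  cl <- classify_patient(records, config)
  status <- data.frame(
    score = cl$points,
    category = cl$category,
    route = cl$route,
    hrtcs_pos = hrtcs_positive(records$wall_thickness, config$wall_cutoff),
    diagnosis = records$final_diagnosis,
    stringsAsFactors = FALSE)
  rows <- lapply(constraints, function(con) {
    keep <- rep(TRUE, nrow(status))
    for (f in names(con$where)) {
      keep <- keep & status[[f]] == con$where[[f]]
    }
    obs <- sum(keep)
    data.frame(label = con$label, expected = con$expected,
               observed = obs, pass = obs == con$expected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
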