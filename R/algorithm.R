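#' Configuration of the stepwise diagnostic algorithm
#'
#' Bundles the CRP cut-off (mg/dL) above which low-probability patients are
#' still imaged, the sonographic wall-thickness cut-off (mm) and the score
#' weights.  Both laboratory cut-offs are inclusive (a CRP of exactly
#' 2.5 mg/dL triggers imaging; a wall of exactly 0.7 mm is positive).
#'
#' @param crp_cutoff CRP cut-off in mg/dL (default 2.5, strictly positive).
#' @param wall_cutoff Wall-thickness cut-off in mm (default 0.7).
#' @param weights A [gca_weights()] object.
#' @return An object of class `gca_config`.
#' @export
gca_config <- function(crp_cutoff = 2.5, wall_cutoff = 0.7,
                       weights = gca_weights()) {
  if (!is.numeric(crp_cutoff) || crp_cutoff <= 0 ||
      !is.numeric(wall_cutoff) || wall_cutoff <= 0) {
    gca_stop("INVALID_CONFIG", "cut-offs must be strictly positive")
  }
  stopifnot(inherits(weights, "gca_weights"))
  structure(list(crp_cutoff = crp_cutoff, wall_cutoff = wall_cutoff,
                 weights = weights),
            class = "gca_config")
}

#' Route patients through the stepwise algorithm
#'
#' Non-low clinical probability (score at or above the category threshold)
#' is referred for temporal artery compression sonography regardless of
#' CRP.  Low-probability patients are imaged only when CRP is at or above
#' the cut-off; otherwise the diagnosis is rejected without imaging.  A
#' low-probability patient with missing CRP cannot be routed and raises an
#' error.
#'
#' @param patients Data frame of patient records.
#' @param config A [gca_config()] object.
#' @return Data frame with columns `points`, `category`, `route`
#'   (`"reject_no_imaging"`, `"hrtcs_low_prob_high_crp"` or
#'   `"hrtcs_non_low_prob"`).
#' @export
route_patient <- function(patients, config = gca_config()) {
  stopifnot(inherits(config, "gca_config"))
  sc <- compute_score(patients, config$weights)
  crp <- patients$crp %||% rep(NA_real_, nrow(patients))
  undecidable <- sc$category == "low" & is.na(crp)
  if (any(undecidable)) {
    ids <- patients$patient_id[undecidable] %||% which(undecidable)
    gca_stop("ROUTE_UNDECIDABLE", paste(
      "CRP missing for low-probability patient(s):",
      paste(utils::head(ids, 5), collapse = ", ")))
  }
  route <- ifelse(sc$category == "non_low", "hrtcs_non_low_prob",
                  ifelse(crp >= config$crp_cutoff,
                         "hrtcs_low_prob_high_crp", "reject_no_imaging"))
  cbind(sc, data.frame(route = route, stringsAsFactors = FALSE))
}

#' Classify patients with the full algorithm
#'
#' Applies [route_patient()] and, on the imaging routes, the sonographic
#' positivity rule: a recorded `hrtcs_result` takes precedence, otherwise
#' the wall thickness is compared against the cut-off.  Patients on the
#' rejection route are classified `cGCA_rejected` without imaging.
#'
#' @inheritParams route_patient
#' @return Data frame with columns `points`, `category`, `route`,
#'   `hrtcs_used` (logical) and `classification` (`"cGCA_suspected"` or
#'   `"cGCA_rejected"`).
#' @export
classify_patient <- function(patients, config = gca_config()) {
  rt <- route_patient(patients, config)
  imaging <- rt$route != "reject_no_imaging"
  hr <- as.character(patients$hrtcs_result %||%
                       rep(NA_character_, nrow(patients)))
  wall <- patients$wall_thickness %||% rep(NA_real_, nrow(patients))
  positive <- ifelse(!is.na(hr), hr == "positive",
                     hrtcs_positive(wall, config$wall_cutoff))
  unusable <- imaging & is.na(positive)
  if (any(unusable)) {
    ids <- patients$patient_id[unusable] %||% which(unusable)
    gca_stop("HRTCS_MISSING", paste(
      "imaging route but neither wall_thickness nor hrtcs_result for:",
      paste(utils::head(ids, 5), collapse = ", ")))
  }
  rt$hrtcs_used <- imaging
  rt$classification <- ifelse(imaging & positive,
                              "cGCA_suspected", "cGCA_rejected")
  rt
}

#' Run a cohort through the algorithm and summarise the patient flow
#'
#' @inheritParams route_patient
#' @return An object of class `gca_flow`: total and per-category counts,
#'   per-route counts, and a route-by-final-diagnosis cross-tabulation.
#' @export
run_cohort <- function(patients, config = gca_config()) {
  if (nrow(patients) == 0) {
    return(structure(list(
      n_total = 0L, n_low = 0L, n_non_low = 0L, n_reject_no_imaging = 0L,
      n_low_imaged = 0L, n_non_low_imaged = 0L,
      routes = data.frame(route = character(), n = integer(),
                          n_cgca = integer(), n_alternative = integer()),
      classified = patients), class = "gca_flow"))
  }
  cl <- classify_patient(patients, config)
  dx <- patients$final_diagnosis
  routes <- c("reject_no_imaging", "hrtcs_low_prob_high_crp",
              "hrtcs_non_low_prob")
  tab <- data.frame(
    route = routes,
    n = vapply(routes, function(r) sum(cl$route == r), integer(1)),
    n_cgca = vapply(routes, function(r)
      sum(cl$route == r & dx == "cGCA"), integer(1)),
    n_alternative = vapply(routes, function(r)
      sum(cl$route == r & dx == "alternative"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    n_total = nrow(patients),
    n_low = sum(cl$category == "low"),
    n_non_low = sum(cl$category == "non_low"),
    n_reject_no_imaging = sum(cl$route == "reject_no_imaging"),
    n_low_imaged = sum(cl$route == "hrtcs_low_prob_high_crp"),
    n_non_low_imaged = sum(cl$route == "hrtcs_non_low_prob"),
    routes = tab,
    classified = cbind(patients, cl)), class = "gca_flow")
}

#' @export
print.gca_flow <- function(x, ...) {
  cat(sprintf("Cohort flow (n = %d)\n", x$n_total))
  cat(sprintf("  low probability:     %3d (%.1f%%)\n", x$n_low,
              if (x$n_total) 100 * x$n_low / x$n_total else 0))
  cat(sprintf("  non-low probability: %3d (%.1f%%)\n", x$n_non_low,
              if (x$n_total) 100 * x$n_non_low / x$n_total else 0))
  cat(sprintf("  rejected, no imaging: %d   low+high CRP imaged: %d   non-low imaged: %d\n",
              x$n_reject_no_imaging, x$n_low_imaged, x$n_non_low_imaged))
  if (nrow(x$routes)) {
    cat("  route x final diagnosis:\n")
    print(x$routes, row.names = FALSE)
  }
  invisible(x)
}
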