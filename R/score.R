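#' Score weights for the clinical prediction rule
#'
#' The rule awards one point each for age above 70 years, new-onset
#' persistent headache and jaw claudication, one point for unilateral and
#' two for bilateral permanent visual impairment due to anterior ischemic
#' optic neuropathy (AION).  Patients with fewer than `category_threshold`
#' points (default 2) are classed as *low* clinical probability, all others
#' as *non-low*.
#'
#' @param age_over_70,headache,jaw_claudication,aion_unilateral,aion_bilateral
#'   Non-negative integer item weights.
#' @param category_threshold Minimum number of points for the non-low
#'   category (>= 1).
#' @return An object of class `gca_weights`.
#' @seealso [compute_score()], [categorize()]
#' @examples
#' gca_weights()
#' gca_weights(aion_bilateral = 3)  # six-point variant
#' @export
gca_weights <- function(age_over_70 = 1L, headache = 1L, jaw_claudication = 1L,
                        aion_unilateral = 1L, aion_bilateral = 2L,
                        category_threshold = 2L) {
  w <- list(
    age_over_70 = as.integer(age_over_70),
    headache = as.integer(headache),
    jaw_claudication = as.integer(jaw_claudication),
    aion_unilateral = as.integer(aion_unilateral),
    aion_bilateral = as.integer(aion_bilateral),
    category_threshold = as.integer(category_threshold)
  )
  bad <- vapply(w, function(v) is.na(v) || v < 0L, logical(1))
  if (any(bad)) {
    gca_stop("INVALID_WEIGHTS", paste("negative or missing weight:",
                                      paste(names(w)[bad], collapse = ", ")))
  }
  if (w$aion_bilateral < w$aion_unilateral) {
    gca_stop("INVALID_WEIGHTS", "aion_bilateral must be >= aion_unilateral")
  }
  if (w$category_threshold < 1L) {
    gca_stop("INVALID_WEIGHTS", "category_threshold must be >= 1")
  }
  structure(w, class = "gca_weights")
}

#' @export
print.gca_weights <- function(x, ...) {
  cat("Clinical prediction rule weights:\n")
  cat(sprintf("  age > 70: %d  headache: %d  jaw claudication: %d\n",
              x$age_over_70, x$headache, x$jaw_claudication))
  cat(sprintf("  AION unilateral: %d  bilateral: %d\n",
              x$aion_unilateral, x$aion_bilateral))
  cat(sprintf("  non-low category at >= %d points\n", x$category_threshold))
  invisible(x)
}

#' Compute the clinical prediction score
#'
#' Sums the item weights for age > 70 years, new-onset headache, jaw
#' claudication and AION laterality.  CRP, wall thickness and the final
#' diagnosis never enter the score.  Age exactly 70 scores 0 points (the
#' model variable is strictly "age > 70").
#'
#' @param patients Data frame of patient records with at least columns
#'   `age`, `new_onset_headache`, `jaw_claudication`, `aion`
#'   (`"none"`/`"unilateral"`/`"bilateral"`).
#' @param weights A [gca_weights()] object.
#' @return Data frame with columns `points` (integer) and `category`
#'   (`"low"` or `"non_low"`), one row per patient.
#' @examples
#' pt <- data.frame(age = 75, new_onset_headache = 1,
#'                  jaw_claudication = 1, aion = "bilateral")
#' compute_score(pt)  # 5 points, non_low
#' @export
compute_score <- function(patients, weights = gca_weights()) {
  stopifnot(inherits(weights, "gca_weights"))
  req <- c("age", "new_onset_headache", "jaw_claudication", "aion")
  for (f in req) {
    if (is.null(patients[[f]])) {
      gca_stop("MISSING_FIELD", paste("required field absent:", f))
    }
    if (anyNA(patients[[f]])) {
      gca_stop("MISSING_FIELD", paste("missing values in required field:", f))
    }
  }
  if (any(patients$age < 0)) gca_stop("INVALID_VALUE", "age must be >= 0")
  aion <- as.character(patients$aion)
  ok <- aion %in% c("none", "unilateral", "bilateral")
  if (!all(ok)) {
    gca_stop("INVALID_VALUE", paste0(
      "unknown AION token(s): ", paste(unique(aion[!ok]), collapse = ", "),
      "; accepted: none, unilateral, bilateral"))
  }
  points <- (patients$age > 70) * weights$age_over_70 +
    (patients$new_onset_headache > 0) * weights$headache +
    (patients$jaw_claudication > 0) * weights$jaw_claudication +
    (aion == "unilateral") * weights$aion_unilateral +
    (aion == "bilateral") * weights$aion_bilateral
  points <- as.integer(points)
  data.frame(points = points,
             category = categorize(points, weights$category_threshold),
             stringsAsFactors = FALSE)
}

#' Map score points to a probability category
#'
#' @param points Non-negative integer score(s).
#' @param threshold Minimum points for the non-low category (default 2, i.e.
#'   low clinical probability is <= 1 point).
#' @return Character vector, `"low"` or `"non_low"`.
#' @examples
#' categorize(0:3)
#' @export
categorize <- function(points, threshold = 2L) {
  if (any(is.na(points)) || any(points < 0)) {
    gca_stop("INVALID_VALUE", "points must be non-negative")
  }
  ifelse(points <= threshold - 1L, "low", "non_low")
}

#' Positivity of temporal artery compression sonography
#'
#' The sonographic test is positive when the summed near- and far-wall
#' thickness of the superficial temporal artery reaches the cut-off
#' (inclusive), 0.7 mm by default.
#'
#' @param wall_thickness Wall thickness in mm (non-negative).
#' @param cutoff Positivity cut-off in mm.
#' @return Logical vector.
#' @examples
#' hrtcs_positive(c(0.69, 0.7, 1.2))
#' @export
hrtcs_positive <- function(wall_thickness, cutoff = 0.7) {
  if (any(!is.na(wall_thickness) & wall_thickness < 0)) {
    gca_stop("INVALID_VALUE", "wall_thickness must be >= 0")
  }
  wall_thickness >= cutoff
}
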