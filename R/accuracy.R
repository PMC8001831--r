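#' Build a 2x2 contingency table from paired predictions and truths
#'
#' @param predictions Logical vector (test positive).
#' @param truths Logical vector (disease present).
#' @return Object of class `gca_table` with integer cells `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
build_table <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    gca_stop("LENGTH_MISMATCH", "predictions and truths differ in length")
  }
  if (length(predictions) == 0) gca_stop("EMPTY_INPUT", "no observations")
  if (anyNA(predictions) || anyNA(truths)) {
    gca_stop("MISSING_FIELD", "NA in predictions or truths")
  }
  predictions <- as.logical(predictions)
  truths <- as.logical(truths)
  contingency(tp = sum(predictions & truths),
              fp = sum(predictions & !truths),
              fn = sum(!predictions & truths),
              tn = sum(!predictions & !truths))
}

#' Construct a 2x2 contingency table from cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true/false
#'   positives/negatives of the index test against the reference
#'   diagnosis).
#' @return Object of class `gca_table`.
#' @export
contingency <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    gca_stop("INVALID_VALUE", "cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "gca_table")
}

#' @export
print.gca_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              diagnosis = c("cGCA", "alternative")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics of a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value and prevalence.  A metric whose denominator is zero is reported
#' as `NA` with its `defined` flag set to `FALSE`, never silently as 0.
#' Wilson score intervals are provided for each defined proportion.
#'
#' @param table A `gca_table` (see [contingency()] / [build_table()]).
#' @param conf_level Confidence level of the Wilson intervals.
#' @return Object of class `gca_metrics`: a data frame with one row per
#'   metric (`estimate`, `defined`, `lower`, `upper`, `numerator`,
#'   `denominator`).
#' @export
metrics <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "gca_table"))
  n <- table$tp + table$fp + table$fn + table$tn
  if (n < 1) gca_stop("EMPTY_INPUT", "empty table")
  one <- function(num, den) {
    if (den == 0) {
      c(estimate = NA_real_, defined = 0, lower = NA_real_,
        upper = NA_real_, numerator = num, denominator = den)
    } else {
      ci <- wilson_ci(num, den, conf_level)
      c(estimate = num / den, defined = 1, lower = ci[1], upper = ci[2],
        numerator = num, denominator = den)
    }
  }
  out <- rbind(
    sensitivity = one(table$tp, table$tp + table$fn),
    specificity = one(table$tn, table$tn + table$fp),
    ppv = one(table$tp, table$tp + table$fp),
    npv = one(table$tn, table$tn + table$fn),
    prevalence = one(table$tp + table$fn, n))
  out <- as.data.frame(out)
  out$defined <- out$defined == 1
  class(out) <- c("gca_metrics", class(out))
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level.
#' @return Length-2 numeric vector, lower and upper bound.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # degenerate counts: the bound touching the point estimate is exact
  c(if (x == 0) 0 else max(0, centre - half),
    if (x == n) 1 else min(1, centre + half))
}

#' ROC curve and AUC of an ordinal score
#'
#' The area under the curve is computed with the midrank (Mann-Whitney)
#' formulation: the probability that a randomly chosen case outscores a
#' randomly chosen non-case, with ties credited one half.  This equals the
#' trapezoidal area over the empirical operating points at all distinct
#' thresholds.
#'
#' @param scores Numeric/ordinal score vector (higher = more disease-like).
#' @param truths Logical vector, disease present.
#' @return Object of class `gca_roc` with the per-threshold operating
#'   points (`threshold`, `sensitivity`, `fpr`) and `auc`.
#' @export
roc_auc <- function(scores, truths) {
  if (length(scores) != length(truths)) {
    gca_stop("LENGTH_MISMATCH", "scores and truths differ in length")
  }
  truths <- as.logical(truths)
  n1 <- sum(truths)
  n0 <- sum(!truths)
  if (n1 == 0 || n0 == 0) {
    gca_stop("SINGLE_CLASS", "both classes must be present for ROC analysis")
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[truths]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # operating points: classify positive at score >= t for each distinct t,
  # bracketed by (0,0) and (1,1)
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) sum(scores[truths] >= t) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores[!truths] >= t) / n0, numeric(1))
  structure(list(
    points = data.frame(threshold = c(Inf, th, -Inf),
                        sensitivity = c(0, sens, 1),
                        fpr = c(0, fpr, 1)),
    auc = auc, n_cases = n1, n_controls = n0), class = "gca_roc")
}

#' @export
print.gca_roc <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls, AUC = %.4f\n",
              x$n_cases, x$n_controls, x$auc))
  invisible(x)
}

#' Reconstruct an integer 2x2 table from published summary statistics
#'
#' Given a stratum size, its number of cases and the printed positive and
#' negative predictive values, searches exhaustively over all integer
#' tables for those whose recomputed PPV and NPV round (half-up, one
#' decimal, percentage scale) to the printed values.  A printed value of
#' `NA` (a "/" in a published table) is interpreted as "undefined", i.e.
#' the corresponding denominator must be zero.
#'
#' @param n Stratum size.
#' @param cases Number of reference-positive subjects in the stratum.
#' @param ppv_pct,npv_pct Printed predictive values in percent (one
#'   decimal), or `NA` for an undefined (zero-denominator) entry.
#' @param label Optional row label used in error messages.
#' @return The unique `gca_table` solution.  If several tables match, the
#'   first is returned with attribute `ambiguous = TRUE` and the full list
#'   in attribute `solutions`.  If none matches, an error identifying the
#'   row is raised.
#' @examples
#' reconstruct_table(39, 1, 50, 100)   # tp 1, fp 1, fn 0, tn 37
#' @export
reconstruct_table <- function(n, cases, ppv_pct, npv_pct, label = NULL) {
  if (cases < 0 || cases > n) gca_stop("INVALID_VALUE", "need 0 <= cases <= n")
  controls <- n - cases
  matches_printed <- function(num, den, printed) {
    if (is.na(printed)) return(den == 0)
    den > 0 && round_half_up(100 * num / den, 1) == round_half_up(printed, 1)
  }
  sols <- list()
  for (tp in 0:cases) {
    for (fp in 0:controls) {
      fn <- cases - tp
      tn <- controls - fp
      if (matches_printed(tp, tp + fp, ppv_pct) &&
          matches_printed(tn, tn + fn, npv_pct)) {
        sols[[length(sols) + 1L]] <- contingency(tp, fp, fn, tn)
      }
    }
  }
  if (length(sols) == 0) {
    gca_stop("INCONSISTENT_ROW", sprintf(
      "no integer 2x2 table reproduces PPV %s / NPV %s for row %s (n=%d, cases=%d)",
      format(ppv_pct), format(npv_pct), label %||% "<unnamed>", n, cases))
  }
  out <- sols[[1]]
  if (length(sols) > 1) {
    attr(out, "ambiguous") <- TRUE
    attr(out, "solutions") <- sols
  } else {
    attr(out, "ambiguous") <- FALSE
  }
  out
}
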