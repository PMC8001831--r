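#' Build the indicator design matrix for model derivation
#'
#' Encodes the candidate items as 0/1 indicators: `age_over_70`,
#' `headache`, `jaw_claudication`, and AION as two mutually exclusive
#' dummies (`aion_unilateral`, `aion_bilateral`) with "none" as the
#' reference level.  The outcome is the final clinical diagnosis.
#'
#' @param patients Data frame of patient records.
#' @return List with `x` (numeric matrix including an `(Intercept)`
#'   column) and `y` (0/1 outcome, 1 = cGCA).
#' @export
design_matrix <- function(patients) {
  aion <- as.character(patients$aion)
  x <- cbind(
    "(Intercept)" = 1,
    age_over_70 = as.numeric(patients$age > 70),
    headache = as.numeric(patients$new_onset_headache > 0),
    jaw_claudication = as.numeric(patients$jaw_claudication > 0),
    aion_unilateral = as.numeric(aion == "unilateral"),
    aion_bilateral = as.numeric(aion == "bilateral"))
  y <- as.numeric(patients$final_diagnosis == "cGCA")
  list(x = x, y = y)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit.  Convergence is declared when the
#' largest absolute coefficient change falls below `tol` (default 1e-8),
#' with an iteration cap of `max_iter` (default 100).  Complete or
#' quasi-complete separation is detected when any coefficient exceeds
#' `separation_bound` (default 15) in absolute value while the likelihood
#' is still improving; the fit is then flagged, not aborted.
#'
#' @param x Numeric design matrix including an intercept column.
#' @param y 0/1 outcome vector.
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Iteration cap.
#' @param separation_bound Absolute coefficient bound that triggers the
#'   separation flag.
#' @return Object of class `gca_logit`: `coefficients`, `se`,
#'   `log_likelihood`, `aic`, `converged`, `n_iterations`, `separation`,
#'   `vcov`, and the per-iteration log-likelihood trace `ll_trace`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L,
                         separation_bound = 15) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    gca_stop("SINGLE_CLASS", "outcome has a single class")
  }
  if (qr(x)$rank < ncol(x)) {
    gca_stop("RANK_DEFICIENT", "design matrix is rank deficient")
  }
  k <- ncol(x)
  beta <- rep(0, k)
  ll <- function(b) {
    eta <- drop(x %*% b)
    # log(1 + exp(eta)) computed stably for large |eta|
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(y * eta - lse)
  }
  ll_trace <- ll(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- drop(solve(xtw %*% x, xtw %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_trace <- c(ll_trace, ll(beta))
    if (any(abs(beta) > separation_bound)) {
      separation <- TRUE
      break
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- t(x * w) %*% x
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(x)
  loglik <- ll(beta)
  structure(list(
    coefficients = beta, se = se, vcov = vcov,
    log_likelihood = loglik, aic = 2 * k - 2 * loglik,
    converged = converged, n_iterations = iter,
    separation = separation, ll_trace = ll_trace,
    n = length(y), k = k), class = "gca_logit")
}

#' @export
print.gca_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, k = %d, logLik = %.3f, AIC = %.2f\n",
              x$n, x$k, x$log_likelihood, x$aic))
  if (x$separation) cat("  WARNING: separation detected, estimates diverge\n")
  print(data.frame(logOR = x$coefficients, SE = x$se))
  invisible(x)
}

#' Wald confidence intervals on the log-odds-ratio scale
#'
#' @param fit A converged [fit_logistic()] object.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `logOR`, `lower`, `upper` per coefficient.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gca_logit"))
  if (!fit$converged) {
    gca_stop("NOT_CONVERGED", "Wald intervals require a converged fit")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(logOR = fit$coefficients,
             lower = fit$coefficients - z * fit$se,
             upper = fit$coefficients + z * fit$se)
}

#' Rank candidate models by AIC
#'
#' Fits a logistic model for each candidate set of indicator columns (an
#' intercept is always included) and ranks the fits by AIC, ties broken
#' first by fewer parameters, then by input order.
#'
#' @param candidates List of character vectors naming columns of the
#'   design matrix (excluding the intercept).
#' @param design A [design_matrix()] list (`x`, `y`).
#' @param ... Passed to [fit_logistic()].
#' @return Object of class `gca_aic_ranking`: `ranking` data frame
#'   (candidate, k, aic, converged, separation) sorted by AIC, `fits`
#'   list in ranked order, `best` the top fit.
#' @export
select_model <- function(candidates, design, ...) {
  if (length(candidates) == 0) gca_stop("EMPTY_INPUT", "no candidate models")
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cols <- candidates[[i]]
    missing_cols <- setdiff(cols, colnames(design$x))
    if (length(missing_cols)) {
      gca_stop("UNKNOWN_VARIABLE", sprintf(
        "candidate %d names unknown column(s): %s", i,
        paste(missing_cols, collapse = ", ")))
    }
    x <- design$x[, c("(Intercept)", cols), drop = FALSE]
    fits[[i]] <- tryCatch(fit_logistic(x, design$y, ...), error = function(e) {
      gca_stop("FIT_FAILED", sprintf("candidate %d (%s): %s", i,
                                     paste(cols, collapse = "+"),
                                     conditionMessage(e)))
    })
  }
  ranking <- data.frame(
    candidate = vapply(candidates, paste, character(1), collapse = "+"),
    k = vapply(fits, function(f) f$k, integer(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    separation = vapply(fits, function(f) f$separation, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(ranking$aic, ranking$k, seq_len(nrow(ranking)))
  structure(list(ranking = ranking[ord, , drop = FALSE],
                 fits = fits[ord], best = fits[[ord[1]]]),
            class = "gca_aic_ranking")
}

#' @export
print.gca_aic_ranking <- function(x, ...) {
  cat("AIC ranking of candidate models:\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Univariate group comparison
#'
#' Compares a candidate variable between patients with and without the
#' final diagnosis: Pearson chi-squared without continuity correction for
#' categorical variables, two-sided Mann-Whitney U with normal
#' approximation and tie correction for continuous ones.
#'
#' @param patients Data frame of patient records.
#' @param variable Column name to compare.
#' @param type `"categorical"` or `"continuous"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
univariate_compare <- function(patients, variable,
                               type = c("categorical", "continuous")) {
  type <- match.arg(type)
  v <- patients[[variable]]
  if (is.null(v)) gca_stop("UNKNOWN_VARIABLE", variable)
  g <- patients$final_diagnosis == "cGCA"
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  if (sum(g) == 0 || sum(!g) == 0) {
    gca_stop("SINGLE_CLASS", "both diagnosis groups must be non-empty")
  }
  if (type == "categorical") {
    tt <- table(group = g, level = v)
    res <- suppressWarnings(stats::chisq.test(tt, correct = FALSE))
    list(statistic = unname(res$statistic), p_value = res$p.value,
         test = "pearson_chi_squared")
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(v[g], v[!g], exact = FALSE, correct = FALSE))
    list(statistic = unname(res$statistic), p_value = res$p.value,
         test = "mann_whitney_u")
  }
}
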