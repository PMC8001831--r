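test_that("IRLS slope on a 2x2 design equals the closed-form log odds ratio", {
  tables <- list(c(16, 10, 2, 59), c(8, 12, 5, 25), c(3, 7, 9, 11))
  for (cells in tables) {
    d <- design_from_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d$x, d$y)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients["slope"]),
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients["(Intercept)"]),
                 log(cells[3] / cells[4]), tolerance = 1e-8)
    # Wald SE has the classical 1/a+1/b+1/c+1/d form for a 2x2
    expect_equal(unname(fit$se["slope"]), sqrt(sum(1 / cells)),
                 tolerance = 1e-6)
  }
})

test_that("AIC of the saturated 2x2 model matches the closed form", {
  d <- design_from_2x2(16, 10, 2, 59)
  fit <- fit_logistic(d$x, d$y)
  p1 <- 16 / 26
  p0 <- 2 / 61
  ll <- 16 * log(p1) + 10 * log(1 - p1) + 2 * log(p0) + 59 * log(1 - p0)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-8)
  expect_equal(fit$aic, 2 * 2 - 2 * ll, tolerance = 1e-8)
})

test_that("degenerate designs raise explicit errors", {
  d <- design_from_2x2(5, 5, 5, 5)
  expect_error(fit_logistic(cbind(d$x, zero = 0), d$y), "RANK_DEFICIENT")
  expect_error(fit_logistic(d$x, rep(1, nrow(d$x))), "SINGLE_CLASS")
})

test_that("separation is flagged, not fatal", {
  x <- cbind("(Intercept)" = 1, v = c(rep(1, 10), rep(0, 10)))
  y <- c(rep(1, 10), rep(0, 10))
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
})

test_that("the log-likelihood never decreases across IRLS iterations", {
  set.seed(23)
  for (i in 1:10) {
    pts <- simulate_cohort(cohort_spec(n = 300, seed = i))
    dm <- design_matrix(pts)
    fit <- fit_logistic(dm$x, dm$y)
    expect_true(all(diff(fit$ll_trace) >= -1e-7))
  }
})

test_that("flipping the outcome labels negates every coefficient", {
  pts <- simulate_cohort(cohort_spec(n = 400, seed = 3))
  dm <- design_matrix(pts)
  f1 <- fit_logistic(dm$x, dm$y)
  f2 <- fit_logistic(dm$x, 1 - dm$y)
  expect_equal(f2$coefficients, -f1$coefficients, tolerance = 1e-6)
  expect_equal(f2$log_likelihood, f1$log_likelihood, tolerance = 1e-8)
})

test_that("the fit matches the reference glm implementation", {
  pts <- simulate_cohort(cohort_spec(n = 600, seed = 8))
  dm <- design_matrix(pts)
  fit <- fit_logistic(dm$x, dm$y)
  ref <- stats::glm.fit(dm$x, dm$y, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$aic, ref$aic, tolerance = 1e-6)
})

test_that("Wald intervals scale with the confidence level", {
  d <- design_from_2x2(16, 10, 2, 59)
  fit <- fit_logistic(d$x, d$y)
  ci95 <- wald_ci(fit, 0.95)
  expect_true(all(ci95$lower <= ci95$logOR & ci95$logOR <= ci95$upper))
  expect_equal(ci95["slope", "upper"] - ci95["slope", "logOR"],
               stats::qnorm(0.975) * fit$se[["slope"]])
  ci0 <- wald_ci(fit, 0)
  expect_equal(ci0$lower, ci0$logOR)
  expect_equal(ci0$upper, ci0$logOR)
})

test_that("select_model ranks by AIC with parsimony tie-break", {
  pts <- simulate_cohort(cohort_spec(n = 500, seed = 12))
  dm <- design_matrix(pts)
  single <- select_model(list(c("headache")), dm)
  expect_identical(nrow(single$ranking), 1L)
  sel <- select_model(list(c("headache", "jaw_claudication"), c("headache")),
                      dm)
  expect_true(all(diff(sel$ranking$aic) >= 0))
  expect_error(select_model(list(c("not_a_column")), dm), "UNKNOWN_VARIABLE")
  expect_error(select_model(list(), dm), "EMPTY_INPUT")
})

test_that("univariate comparisons match direct oracles", {
  # groups arranged to the published derivation jaw-claudication margin
  pts <- rbind(
    do.call(rbind, replicate(16, patient(jaw_claudication = 1L,
                                         final_diagnosis = "cGCA"),
                             simplify = FALSE)),
    do.call(rbind, replicate(10, patient(final_diagnosis = "cGCA"),
                             simplify = FALSE)),
    do.call(rbind, replicate(2, patient(jaw_claudication = 1L),
                             simplify = FALSE)),
    do.call(rbind, replicate(59, patient(), simplify = FALSE)))
  res <- univariate_compare(pts, "jaw_claudication", "categorical")
  expect_equal(res$statistic, chisq_2x2_oracle(16, 10, 2, 59),
               tolerance = 1e-10)
  # identical groups: no signal
  same <- rbind(patient(final_diagnosis = "cGCA"),
                patient(final_diagnosis = "cGCA", jaw_claudication = 1L),
                patient(), patient(jaw_claudication = 1L))
  res0 <- univariate_compare(same, "jaw_claudication", "categorical")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # Mann-Whitney U on fully separated groups: U = 0 (or 9 by symmetry)
  cont <- rbind(
    do.call(rbind, lapply(4:6, function(v)
      patient(crp = v, final_diagnosis = "cGCA"))),
    do.call(rbind, lapply(1:3, function(v) patient(crp = v))))
  resu <- univariate_compare(cont, "crp", "continuous")
  expect_true(resu$statistic %in% c(0, 9))
})
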