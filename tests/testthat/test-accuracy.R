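test_that("build_table counts prediction/truth pairs", {
  tab <- build_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_identical(unlist(tab[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 0L, tn = 1L))
  all5 <- build_table(rep(TRUE, 5), rep(TRUE, 5))
  expect_identical(all5$tp, 5L)
  expect_identical(all5$fp + all5$fn + all5$tn, 0L)
  expect_error(build_table(TRUE, c(TRUE, FALSE)), "LENGTH_MISMATCH")
  expect_error(build_table(logical(), logical()), "EMPTY_INPUT")
})

test_that("the derivation non-low stratum gives PPV 21/23 by direct enumeration", {
  pts <- build_fixture("derivation")
  cl <- classify_patient(pts)
  keep <- cl$category == "non_low"
  tab <- build_table(hrtcs_positive(pts$wall_thickness)[keep],
                     (pts$final_diagnosis == "cGCA")[keep])
  expect_identical(c(tab$tp, tab$fp), c(21L, 2L))
  m <- metrics(tab)
  expect_equal(m["ppv", "estimate"], 21 / 23)
  expect_equal(m["npv", "estimate"], 8 / 11)
})

test_that("metrics reproduce the published stratum predictive values", {
  m1 <- metrics(contingency(29, 5, 0, 20))
  expect_equal(round_half_up(100 * m1["ppv", "estimate"], 1), 85.3)
  expect_equal(m1["npv", "estimate"], 1.0)
  m2 <- metrics(contingency(9, 4, 2, 24))
  expect_equal(round_half_up(100 * m2["ppv", "estimate"], 1), 69.2)
  expect_equal(round_half_up(100 * m2["npv", "estimate"], 1), 92.3)
  expect_equal(m2["prevalence", "estimate"], 11 / 39)
})

test_that("zero-denominator metrics are flagged undefined, never silently 0", {
  m <- metrics(contingency(0, 0, 0, 4))
  expect_false(m["ppv", "defined"])
  expect_true(is.na(m["ppv", "estimate"]))
  expect_true(m["npv", "defined"])
  expect_equal(m["npv", "estimate"], 1.0)
  expect_false(m["sensitivity", "defined"])
})

test_that("wilson intervals contain the point estimate and stay in [0,1]", {
  for (xy in list(c(1, 2), c(29, 34), c(0, 10), c(10, 10))) {
    ci <- wilson_ci(xy[1], xy[2])
    p <- xy[1] / xy[2]
    expect_true(ci[1] <= p && p <= ci[2])
    expect_true(ci[1] >= 0 && ci[2] <= 1)
  }
})

test_that("reconstruction recovers the published consistent strata", {
  t0 <- reconstruct_table(39, 1, 50, 100, label = "score 0")
  expect_identical(unlist(t0[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 0L, tn = 37L))
  expect_false(attr(t0, "ambiguous"))
  t3 <- reconstruct_table(17, 10, 75, 80, label = "score 3")
  expect_identical(unlist(t3[c("tp", "fp", "fn", "tn")]),
                   c(tp = 9L, fp = 3L, fn = 1L, tn = 4L))
  t2 <- reconstruct_table(39, 11, 69.2, 92.3, label = "score 2")
  expect_identical(unlist(t2[c("tp", "fp", "fn", "tn")]),
                   c(tp = 9L, fp = 4L, fn = 2L, tn = 24L))
  # caseless stratum with undefined PPV: zero test-positives
  tc <- reconstruct_table(10, 0, NA, 100)
  expect_identical(tc$tn, 10L)
  expect_identical(tc$tp + tc$fp + tc$fn, 0L)
})

test_that("metrics of a reconstructed table round-trip to the printed values", {
  rows <- list(list(n = 39, cases = 1, ppv = 50, npv = 100),
               list(n = 39, cases = 11, ppv = 69.2, npv = 92.3),
               list(n = 17, cases = 10, ppv = 75, npv = 80))
  for (r in rows) {
    tab <- reconstruct_table(r$n, r$cases, r$ppv, r$npv)
    m <- metrics(tab)
    expect_equal(round_half_up(100 * m["ppv", "estimate"], 1),
                 round_half_up(r$ppv, 1))
    expect_equal(round_half_up(100 * m["npv", "estimate"], 1),
                 round_half_up(r$npv, 1))
    expect_identical(tab$tp + tab$fn, as.integer(r$cases))
  }
})

test_that("reconstruction rejects rows no integer table can produce", {
  expect_error(reconstruct_table(74, 2, 11.1, 98.4, label = "score 1"),
               "INCONSISTENT_ROW.*score 1")
  expect_error(reconstruct_table(53, 2, 50, 98.4, label = "low stratum"),
               "INCONSISTENT_ROW")
})
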