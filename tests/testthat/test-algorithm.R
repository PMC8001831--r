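test_that("routing follows the score category and the inclusive CRP cut-off", {
  p3 <- patient(age = 75, new_onset_headache = 1L, aion = "unilateral",
                crp = 0.4)
  expect_identical(route_patient(p3)$route, "hrtcs_non_low_prob")
  p1 <- patient(new_onset_headache = 1L, crp = 2.5)
  expect_identical(route_patient(p1)$route, "hrtcs_low_prob_high_crp")
  expect_identical(route_patient(patient(crp = 0))$route, "reject_no_imaging")
  expect_identical(route_patient(patient(crp = 2.49))$route,
                   "reject_no_imaging")
})

test_that("missing CRP makes a low-probability patient unroutable, not a non-low one", {
  low <- patient(crp = NA_real_)
  expect_error(route_patient(low), "ROUTE_UNDECIDABLE.*P1")
  high <- patient(age = 75, new_onset_headache = 1L, crp = NA_real_)
  expect_identical(route_patient(high)$route, "hrtcs_non_low_prob")
})

test_that("classification applies sonography only on imaging routes", {
  # low probability, low CRP: rejected without using the (positive) probe
  p <- patient(crp = 1.0, wall_thickness = 1.1, hrtcs_result = "positive")
  out <- classify_patient(p)
  expect_identical(out$classification, "cGCA_rejected")
  expect_false(out$hrtcs_used)
  # non-low with thick wall: suspected
  p4 <- patient(age = 75, new_onset_headache = 1L, jaw_claudication = 1L,
                aion = "unilateral", wall_thickness = 0.9)
  out4 <- classify_patient(p4)
  expect_identical(out4$classification, "cGCA_suspected")
  expect_true(out4$hrtcs_used)
  # imaged low-probability patient with thin wall: rejected after imaging
  p1 <- patient(new_onset_headache = 1L, crp = 3.0, wall_thickness = 0.5)
  out1 <- classify_patient(p1)
  expect_identical(out1$classification, "cGCA_rejected")
  expect_true(out1$hrtcs_used)
})

test_that("an imaging route without any sonographic datum is an explicit error", {
  p <- patient(age = 75, new_onset_headache = 1L, jaw_claudication = 1L,
               wall_thickness = NA_real_, hrtcs_result = NA_character_)
  expect_error(classify_patient(p), "HRTCS_MISSING.*P1")
})

test_that("cohort flows of both fixtures match the published counts", {
  fd <- run_cohort(build_fixture("derivation"))
  expect_identical(fd$n_total, 87L)
  expect_identical(fd$n_low, 53L)
  expect_identical(fd$n_non_low, 34L)
  expect_identical(fd$n_low_imaged, 25L)
  expect_identical(fd$n_reject_no_imaging, 28L)
  fv <- run_cohort(build_fixture("validation"))
  expect_identical(fv$n_total, 114L)
  expect_identical(fv$n_low, 60L)
  expect_identical(fv$n_non_low, 54L)
  expect_identical(fv$n_low_imaged, 4L)
  expect_identical(fv$n_reject_no_imaging, 56L)
})

test_that("no rejected patient in either fixture carries a cGCA diagnosis", {
  for (ch in c("derivation", "validation")) {
    flow <- run_cohort(build_fixture(ch))
    rej <- flow$routes[flow$routes$route == "reject_no_imaging", ]
    expect_identical(rej$n_cgca, 0L)
  }
})

test_that("an empty cohort yields an all-zero flow", {
  flow <- run_cohort(build_fixture("derivation")[0, ])
  expect_identical(flow$n_total, 0L)
  expect_identical(flow$n_low + flow$n_non_low, 0L)
})

test_that("routes partition every cohort", {
  for (ch in c("derivation", "validation")) {
    flow <- run_cohort(build_fixture(ch))
    expect_identical(sum(flow$routes$n), flow$n_total)
    expect_identical(flow$n_low, flow$n_reject_no_imaging + flow$n_low_imaged)
    expect_identical(flow$n_non_low, flow$n_non_low_imaged)
  }
})

test_that("raising the CRP cut-off never shrinks the rejection set", {
  pts <- build_fixture("derivation")
  prev <- NULL
  for (cut in c(0.5, 1.0, 2.5, 5.0, 10.0)) {
    rt <- route_patient(pts, gca_config(crp_cutoff = cut))
    rejected <- pts$patient_id[rt$route == "reject_no_imaging"]
    if (!is.null(prev)) expect_true(all(prev %in% rejected))
    prev <- rejected
  }
})
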