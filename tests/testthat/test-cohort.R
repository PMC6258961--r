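test_that("default cohort matches the training-database sizes", {
  co <- simulate_cohort(cohort_spec(seed = 61))
  expect_equal(nrow(co), 591L)
  expect_equal(sum(co$label == "control"), 402L)
  expect_equal(sum(co$label == "doped"), 189L)
  expect_silent(validate_profiles(co))
})

test_that("empty cohorts and invalid specs are handled", {
  co <- simulate_cohort(cohort_spec(n_control = 0, n_doped = 0))
  expect_equal(nrow(co), 0L)
  expect_error(cohort_spec(n_control = -1), ">= 0")
  bad <- matrix(c(1, 2, 0, 0, 2, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1), 4, 4,
                dimnames = rep(list(c("HGB", "RBC", "MCV", "RETP")), 2))
  expect_error(cohort_spec(log_corr = bad), "positive definite")
})

test_that("the same seed reproduces a cohort bit-identically", {
  a <- simulate_cohort(cohort_spec(seed = 62))
  b <- simulate_cohort(cohort_spec(seed = 62))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_spec(seed = 63))
  expect_false(identical(a, c))
})

test_that("generated profiles respect the hematological identities", {
  co <- simulate_cohort(cohort_spec(n_control = 3000, n_doped = 2000,
                                    seed = 64))
  expect_true(all(abs(co$MCHC - co$HGB / co$HCT * 100) <= 2))
  expect_true(all(abs(co$MCV - co$HCT / co$RBC * 10) <= 8))
  expect_true(all(as.matrix(co[abps_markers()]) > 0))
})

test_that("doped effects act in the documented directions", {
  co <- simulate_cohort(cohort_spec(seed = 65))
  ctrl <- co$label == "control"
  expect_gt(mean(co$HGB[!ctrl]), mean(co$HGB[ctrl]))
  off <- !ctrl & co$phase == "off"
  on <- !ctrl & co$phase == "on"
  expect_lt(mean(co$RETP[off]), mean(co$RETP[ctrl]))
  expect_gt(mean(co$RETP[on]), mean(co$RETP[ctrl]))
})

test_that("a null doped effect produces no spurious separation", {
  spec <- cohort_spec(seed = 66,
                      doped_shift = c(HGB = 1, RBC = 1, MCV = 1),
                      retp_on = 1, retp_off = 1, variance_inflation = 1)
  co <- simulate_cohort(spec)
  set.seed(66)
  idx <- sample(nrow(co), round(0.7 * nrow(co)))
  fit <- suppressWarnings(abps_fit(co[idx, ], seed = 66))
  s <- suppressWarnings(predict(fit, co[-idx, ], type = "abps"))
  a <- bloodscore:::auroc(s, co$label[-idx] == "doped")
  expect_gte(a, 0.4)
  expect_lte(a, 0.6)
})

test_that("fixtures are deterministic and behave as designed", {
  c13 <- make_fixture("control13")
  d13 <- make_fixture("doping13")
  expect_equal(nrow(c13), 13L)
  expect_equal(nrow(d13), 13L)
  expect_identical(c13, make_fixture("control13"))
  expect_identical(d13, make_fixture("doping13"))
  expect_true(!is.unsorted(d13$date))
  expect_error(make_fixture("nope"))

  fit <- default_model_cache()
  sc <- suppressWarnings(score_profiles(c13, fit))
  expect_true(all(sc$band %in% c("typical", "suspicion")))
  sd13 <- suppressWarnings(score_profiles(d13, fit))
  # hemoglobin rises and reticulocytes collapse: the series ends abnormal
  expect_equal(as.character(sd13$band[13]), "abnormal")
  expect_true(all(diff(sign(sd13$abps)) >= 0))
})
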