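# Full ensemble pipeline: fitting, scoring, bands, persistence.

test_that("ensemble averaging standardizes then averages the components", {
  std <- list(center = c(nb = 2, svm = -1), scale = c(nb = 2, svm = 0.5))
  # components standardizing to +1 and -1 average to zero
  expect_identical(ensemble_average(4, -1.5, std), 0)
  # equal standardized components average to themselves
  expect_equal(ensemble_average(2 + 2 * 1.3, -1 + 0.5 * 1.3, std), 1.3)
  # 5-sample table against a hand recomputation
  nb_raw <- c(-1.2, 0.4, 2.0, 3.6, -0.8)
  svm_raw <- c(-0.9, -0.2, 0.3, 1.4, 0.1)
  std2 <- list(center = c(mean(nb_raw), mean(svm_raw)),
               scale = c(sd(nb_raw), sd(svm_raw)))
  by_hand <- (scale(nb_raw)[, 1] + scale(svm_raw)[, 1]) / 2
  expect_equal(ensemble_average(nb_raw, svm_raw, std2), by_hand,
               tolerance = 1e-12)
  expect_error(ensemble_average(1, 1, list(center = c(0, 0),
                                           scale = c(0, 1))), "zero")
})

test_that("decision bands follow the published boundaries", {
  expect_equal(as.character(classify_band(0.5)), "suspicion")
  expect_equal(as.character(classify_band(1.2)), "abnormal")
  expect_equal(as.character(classify_band(-0.67)), "typical")
  # boundaries: suspicion is the closed interval [0, 1]
  expect_equal(as.character(classify_band(c(0, 1, 1 + 1e-9, -1e-9))),
               c("suspicion", "suspicion", "abnormal", "typical"))
  expect_error(classify_band(NA_real_), "finite")
})

test_that("scoring the calibration population recovers the reference mean", {
  fit <- default_model_cache()
  co <- simulate_cohort(cohort_spec(seed = 1))
  s <- suppressWarnings(predict(fit, co[co$label == "control", ],
                                type = "abps"))
  expect_equal(mean(s), -0.67, tolerance = 0.05)
  expect_equal(sd(s), 0.87, tolerance = 0.05)
})

test_that("permuting input rows permutes scores identically", {
  fit <- default_model_cache()
  co <- simulate_cohort(cohort_spec(n_control = 30, n_doped = 20, seed = 44))
  set.seed(44)
  perm <- sample(nrow(co))
  s <- suppressWarnings(score_profiles(co, fit))
  sp <- suppressWarnings(score_profiles(co[perm, ], fit))
  expect_identical(sp$abps, s$abps[perm])
  expect_identical(sp$sample_id, s$sample_id[perm])
})

test_that("a profile and its pre-clipped copy score identically", {
  fit <- default_model_cache()
  p <- data.frame(sample_id = "x", HCT = 60, HGB = 19.5, MCH = 29,
                  MCHC = 32.5, MCV = 89, RBC = 7.2, RETP = 0.05)
  pc <- suppressWarnings(clip_profiles(p))
  s1 <- suppressWarnings(score_profiles(p, fit))
  s2 <- suppressWarnings(score_profiles(pc, fit))
  expect_identical(s1$abps, s2$abps)
})

test_that("invalid rows are skipped with diagnostics; fully invalid input gives empty output", {
  fit <- default_model_cache()
  co <- simulate_cohort(cohort_spec(n_control = 5, n_doped = 0, seed = 45))
  co$HGB[2] <- NA
  w <- testthat::capture_warnings(s <- score_profiles(co, fit))
  expect_match(w, "row 2.*HGB.*skipped", all = FALSE)
  expect_equal(nrow(s), 4L)
  co$HGB <- NA
  out <- suppressWarnings(score_profiles(co, fit))
  expect_equal(nrow(out), 0L)
})

test_that("both ensemble components carry signal on held-out data", {
  skip_if_not_installed("pROC")
  fit <- default_model_cache()
  te <- simulate_cohort(cohort_spec(n_control = 150, n_doped = 80,
                                    seed = 46))
  comp <- suppressWarnings(predict(fit, te, type = "components"))
  lab <- te$label == "doped"
  a_nb <- bloodscore:::auroc(comp$nb_raw, lab)
  a_svm <- bloodscore:::auroc(comp$svm_raw, lab)
  expect_gt(a_nb, 0.5)
  expect_gt(a_svm, 0.5)
  # internal rank AUROC agrees with pROC
  ref <- as.numeric(pROC::auc(pROC::roc(lab, comp$nb_raw, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a_nb, ref, tolerance = 1e-12)
})

test_that("same cohort, seed and config give bit-identical scores", {
  co <- simulate_cohort(cohort_spec(n_control = 120, n_doped = 60, seed = 47))
  f1 <- suppressWarnings(abps_fit(co, seed = 47))
  f2 <- suppressWarnings(abps_fit(co, seed = 47))
  probe <- simulate_cohort(cohort_spec(n_control = 20, n_doped = 10,
                                       seed = 48))
  expect_identical(suppressWarnings(predict(f1, probe)),
                   suppressWarnings(predict(f2, probe)))
})

test_that("save/load round trip reproduces scores bit-exactly", {
  fit <- default_model_cache()
  f <- withr::local_tempfile(fileext = ".json")
  save_abps_model(fit, f)
  fit2 <- load_abps_model(f)
  probe <- simulate_cohort(cohort_spec(n_control = 80, n_doped = 20,
                                       seed = 49))
  expect_identical(suppressWarnings(predict(fit, probe)),
                   suppressWarnings(predict(fit2, probe)))
})

test_that("loading a corrupt or mismatched model file is a hard error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("", f)
  expect_error(load_abps_model(f), "parse|schema")
  writeLines('{"schema": "bloodscore-model/999"}', f)
  expect_error(load_abps_model(f), "schema mismatch")
  expect_error(load_abps_model(file.path(tempdir(), "nope.json")),
               "not found")
})

test_that("a model saved with a different marker order loads to identical scores", {
  fit <- default_model_cache()
  f <- withr::local_tempfile(fileext = ".json")
  save_abps_model(fit, f)
  obj <- jsonlite::read_json(f)
  perm <- c(3, 1, 7, 2, 5, 4, 6)
  obj$markers <- obj$markers[perm]
  obj$svm$markers <- obj$svm$markers[perm]
  obj$svm$center <- obj$svm$center[perm]
  obj$svm$scale <- obj$svm$scale[perm]
  obj$svm_sv <- lapply(obj$svm_sv, function(row) row[perm])
  obj$nb$densities <- lapply(obj$nb$densities, function(cl) cl[perm])
  obj$ranges <- obj$ranges[perm]
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, digits = I(17), auto_unbox = TRUE)
  fit2 <- load_abps_model(f2)
  probe <- simulate_cohort(cohort_spec(n_control = 30, n_doped = 0,
                                       seed = 50))
  expect_identical(suppressWarnings(predict(fit, probe)),
                   suppressWarnings(predict(fit2, probe)))
})

test_that("print, summary and plot methods run", {
  fit <- default_model_cache()
  expect_output(print(fit), "Abnormal Blood Profile Score model")
  co <- simulate_cohort(cohort_spec(n_control = 40, n_doped = 20, seed = 51))
  sm <- suppressWarnings(summary(fit, data = co))
  expect_output(print(sm), "AUROC")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(suppressWarnings(plot(fit, data = co)))
})
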