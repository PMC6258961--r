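test_that("CSV round trip preserves profiles in order", {
  p <- random_profiles(3)
  p <- cbind(sample_id = c("a", "b", "c"), round(p, 3), site = "lab1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(p, f)
  q <- read_profiles(f, quiet = TRUE)
  expect_equal(q$sample_id, p$sample_id)
  for (m in abps_markers()) expect_identical(q[[m]], p[[m]])
  expect_equal(q$site, p$site)  # extra columns preserved
})

test_that("missing marker column is a hard error naming the column", {
  p <- random_profiles(2)
  p$RETP <- NULL
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(p, f, row.names = FALSE)
  expect_error(read_profiles(f, quiet = TRUE), "missing marker: RETP")
})

test_that("rows with missing marker values are rejected, others kept", {
  p <- round(random_profiles(3), 2)
  p$HGB <- as.character(p$HGB)
  p$HGB[2] <- "NA"
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(p, f, row.names = FALSE, quote = FALSE)
  expect_warning(q <- read_profiles(f, quiet = TRUE), "row 2.*HGB.*rejected")
  expect_equal(nrow(q), 2L)
  expect_equal(attr(q, "n_rejected"), 1L)
  expect_equal(q$sample_id, c("1", "3"))
})

test_that("empty input yields an empty profile set with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), f)
  expect_warning(q <- read_profiles(f, quiet = TRUE), "empty")
  expect_equal(nrow(q), 0L)
})

test_that("marker columns match case-insensitively and in any order", {
  p <- round(random_profiles(2), 2)
  names(p) <- tolower(names(p))
  p <- p[rev(names(p))]
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(p, f, row.names = FALSE)
  q <- read_profiles(f, quiet = TRUE)
  expect_equal(q$HGB, p$hgb)
})

test_that("clipping replaces out-of-range values by the nearest bound", {
  p <- data.frame(HCT = 43, HGB = 12.0, MCH = 29, MCHC = 32.5,
                  MCV = 89, RBC = 4.8, RETP = 1.1)
  expect_warning(q <- clip_profiles(p), "clipped")
  expect_identical(q$HGB, 12.9)
  ev <- attr(q, "clip_events")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$marker, "HGB")
  expect_equal(ev$original, 12.0)

  p$HGB <- 19.0
  expect_warning(q <- clip_profiles(p), "clipped")
  expect_identical(q$HGB, 18.2)

  p$HGB <- 15.0   # in range: identity, no warning, no events
  expect_silent(q <- clip_profiles(p))
  expect_identical(q$HGB, 15.0)
  expect_equal(nrow(attr(q, "clip_events")), 0L)
})

test_that("clipping is idempotent and order-preserving", {
  set.seed(42)
  p <- random_profiles(2000)
  q1 <- clip_profiles(p, warn = FALSE)
  q2 <- clip_profiles(q1, warn = FALSE)
  attr(q1, "clip_events") <- attr(q2, "clip_events") <- NULL
  expect_identical(q1, q2)
  r <- marker_ranges()
  for (m in abps_markers()) {
    expect_true(all(q1[[m]] >= r[[m]][1] & q1[[m]] <= r[[m]][2]))
    o <- order(p[[m]])
    expect_true(!is.unsorted(q1[[m]][o]))  # monotone per marker
  }
})

test_that("unit heuristics flag g/L hemoglobin, fractional HCT, absolute RETP", {
  base <- data.frame(HCT = 43, HGB = 14.5, MCH = 29, MCHC = 32.5,
                     MCV = 89, RBC = 4.8, RETP = 1.1)
  expect_equal(nrow(check_units(base)), 0L)

  p <- base; p$HGB <- 145   # looks like g/L
  w <- check_units(p)
  expect_equal(w$marker, "HGB")

  p <- base; p$HCT <- 0.43  # looks like a fraction
  w <- check_units(p)
  expect_equal(w$marker, "HCT")

  p <- base; p$RETP <- 60   # looks like an absolute count
  w <- check_units(p)
  expect_equal(w$marker, "RETP")
})

test_that("validation rejects non-positive and non-finite markers", {
  p <- random_profiles(2)
  p$MCV[1] <- -1
  expect_error(validate_profiles(p), "MCV")
  p <- random_profiles(2)
  p$RBC[2] <- NaN
  expect_error(validate_profiles(p), "RBC")
  expect_error(marker_ranges(HGB = c(5, 4)), "lower < upper")
})
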