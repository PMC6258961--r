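#' Fit an Abnormal Blood Profile Score model
#'
#' Trains the two-classifier ensemble behind the ABPS: a kernel-density
#' naive Bayes classifier and an RBF-kernel SVM, each fitted on the seven
#' clipped hematological markers of a labeled cohort. The two raw component
#' scores are combined by ensemble averaging — each is centered and scaled
#' by its control-population moments, then the two standardized scores are
#' averaged — and the combined score is passed through a monotone quantile
#' calibration map fitted on the training controls so that a clean
#' reference population reproduces the published score distribution
#' (mean -0.67, sd 0.87, 95% of values between -2.35 and 1).
#'
#' Scores above 1 are abnormal (expected in only 1 in 1,000 clean male
#' athletes); scores between 0 and 1 indicate possible suspicion of doping;
#' lower scores are typical.
#'
#' @param data Data frame with the seven marker columns (HCT, HGB, MCH,
#'   MCHC, MCV, RBC, RETP) and a label column.
#' @param label Name of the label column (values `control` / `doped`), or a
#'   vector of labels. Default `"label"`.
#' @param C,width SVM cost and RBF kernel width (see [train_svm()]).
#' @param priors Naive Bayes class priors (see [train_naive_bayes()]).
#' @param ranges [marker_ranges()] used to clip marker values.
#' @param reference Calibration preset name or [reference_spec()].
#' @param calibrate Fit the calibration map on the training controls?
#'   Requires at least 100 controls. With `FALSE` the model returns raw
#'   ensemble-averaged scores.
#' @param seed Optional seed (stored in the model metadata and set before
#'   training).
#' @return An object of class `abps_model` with components `nb`, `svm`,
#'   `component_center`, `component_scale`, `calibration`, `ranges`, and
#'   training metadata. Methods: [print()], [summary()], [predict()],
#'   [plot()].
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' fit <- abps_fit(cohort, seed = 1)
#' print(fit)
#' head(predict(fit, cohort))
#' }
#' @seealso [score_profiles()], [simulate_cohort()], [save_abps_model()]
#' @export
abps_fit <- function(data, label = "label", C = 1, width = "auto",
                     priors = c(control = 0.5, doped = 0.5),
                     ranges = marker_ranges(),
                     reference = "reference_all",
                     calibrate = TRUE, seed = NULL) {
  if (length(label) == 1L && is.character(label)) {
    if (!label %in% names(data))
      stop("label column '", label, "' not found")
    y <- data[[label]]
  } else {
    y <- label
  }
  y <- as_label(y, nrow(data))
  validate_profiles(data)
  clipped <- clip_profiles(data, ranges, warn = FALSE)
  x <- as_feature_matrix(clipped, .MARKERS)

  if (!is.null(seed)) set.seed(seed)
  nb <- train_naive_bayes(x, y, priors = priors)
  svm <- train_svm(x, y, C = C, width = width, seed = seed)

  ctrl <- y == "control"
  comp <- cbind(nb = nb_score(nb, x), svm = svm_decision(svm, x))
  center <- colMeans(comp[ctrl, , drop = FALSE])
  scale <- apply(comp[ctrl, , drop = FALSE], 2L, stats::sd)
  if (any(scale == 0))
    stop("zero component scale on training controls")

  model <- structure(list(
    nb = nb, svm = svm,
    component_center = center, component_scale = scale,
    calibration = NULL,
    ranges = ranges,
    n_control = sum(ctrl), n_doped = sum(!ctrl),
    seed = seed, markers = .MARKERS,
    version = as.character(utils::packageVersion("bloodscore"))
  ), class = "abps_model")

  if (isTRUE(calibrate)) {
    raw_ctrl <- ensemble_average(comp[ctrl, "nb"], comp[ctrl, "svm"],
                                 list(center = center, scale = scale))
    model$calibration <- calibrate_scores(raw_ctrl, reference)
  }
  model
}

#' Ensemble averaging of the two component scores
#'
#' Combines a naive Bayes raw score and an SVM raw score into one raw ABPS
#' by standardizing each with its control-population center and scale and
#' taking their mean.
#'
#' @param nb_raw,svm_raw Numeric raw component scores.
#' @param standardization List with numeric `center` and `scale`, each of
#'   length 2 (order: nb, svm), fitted on training controls.
#' @return Numeric vector of raw ensemble scores.
#' @export
ensemble_average <- function(nb_raw, svm_raw, standardization) {
  ctr <- standardization$center; scl <- standardization$scale
  if (length(ctr) != 2L || length(scl) != 2L)
    stop("standardization needs center and scale of length 2 (nb, svm)")
  if (any(scl == 0)) stop("zero component scale")
  ((nb_raw - ctr[[1]]) / scl[[1]] + (svm_raw - ctr[[2]]) / scl[[2]]) / 2
}

#' Decision bands for calibrated ABPS scores
#'
#' @param abps Numeric calibrated score(s).
#' @return Factor with levels `typical` (< 0), `suspicion` (0 to 1,
#'   inclusive), `abnormal` (> 1).
#' @examples
#' classify_band(c(-0.67, 0.5, 1.2))
#' @export
classify_band <- function(abps) {
  if (any(!is.finite(abps))) stop("abps scores must be finite")
  factor(ifelse(abps > 1, "abnormal",
                ifelse(abps >= 0, "suspicion", "typical")),
         levels = c("typical", "suspicion", "abnormal"))
}

#' Score blood profiles with a trained model
#'
#' Runs the full scoring pipeline on each profile: validate, clip to the
#' model's marker ranges (with warnings for clipped values), compute the
#' naive Bayes and SVM raw scores, ensemble-average, apply the calibration
#' map, and assign a decision band. Rows failing validation are skipped
#' with a per-row diagnostic; output order follows input order.
#'
#' @param profiles Data frame of blood profiles (e.g. [read_profiles()]).
#' @param model A trained `abps_model`.
#' @return Data frame with columns `sample_id`, `abps`, `band`.
#' @export
score_profiles <- function(profiles, model) {
  stopifnot(inherits(model, "abps_model"))
  ids <- if ("sample_id" %in% names(profiles))
    as.character(profiles$sample_id) else as.character(seq_len(nrow(profiles)))
  ok <- rep(TRUE, nrow(profiles))
  for (m in .MARKERS) {
    if (!m %in% names(profiles))
      stop("missing marker: ", m)
    v <- suppressWarnings(as.numeric(profiles[[m]]))
    bad <- !is.finite(v) | v <= 0
    for (i in which(bad & ok))
      warning("row ", i, " (", ids[i], "): invalid ", m, "; row skipped",
              call. = FALSE)
    ok <- ok & !bad
    profiles[[m]] <- v
  }
  keep <- profiles[ok, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(sample_id = character(), abps = numeric(),
                      band = factor(levels = c("typical", "suspicion",
                                               "abnormal"))))
  s <- predict(model, keep, type = "abps")
  data.frame(sample_id = ids[ok], abps = s, band = classify_band(s),
             row.names = NULL)
}

#' Predict method for ABPS models
#'
#' @param object A trained `abps_model`.
#' @param newdata Data frame of blood profiles.
#' @param type `"abps"` (calibrated scores, the default), `"band"`
#'   (decision bands), `"raw"` (uncalibrated ensemble average), or
#'   `"components"` (data frame with all intermediate scores).
#' @param ... Unused.
#' @return Numeric vector, factor, or data frame according to `type`.
#' @export
predict.abps_model <- function(object, newdata,
                               type = c("abps", "band", "raw", "components"),
                               ...) {
  type <- match.arg(type)
  validate_profiles(newdata)
  clipped <- clip_profiles(newdata, object$ranges, warn = TRUE)
  x <- as_feature_matrix(clipped, object$markers)
  nb_raw <- nb_score(object$nb, x)
  svm_raw <- svm_decision(object$svm, x)
  raw <- ensemble_average(nb_raw, svm_raw,
                          list(center = object$component_center,
                               scale = object$component_scale))
  if (type == "raw") return(raw)
  if (type == "components" || type %in% c("abps", "band")) {
    abps <- if (is.null(object$calibration)) raw else
      apply_calibration(object$calibration, raw)
  }
  switch(type,
         abps = abps,
         band = classify_band(abps),
         components = data.frame(nb_raw = nb_raw, svm_raw = svm_raw,
                                 raw = raw, abps = abps,
                                 band = classify_band(abps)))
}

#' @export
print.abps_model <- function(x, ...) {
  cat("Abnormal Blood Profile Score model\n")
  cat("  markers: ", paste(x$markers, collapse = ", "), "\n", sep = "")
  cat("  training: ", x$n_control, " control + ", x$n_doped,
      " doped profiles", if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"),
      "\n", sep = "")
  cat("  SVM: RBF width ", format(x$svm$width, digits = 4), ", C = ",
      format(x$svm$C), ", ", nrow(x$svm$sv), " support vectors\n", sep = "")
  cat("  calibration: ",
      if (is.null(x$calibration)) "none (raw ensemble scores)" else
        paste0("'", x$calibration$spec$name, "' (",
               length(x$calibration$knots_x), " knots)"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.abps_model <- function(object, data = NULL, label = "label", ...) {
  out <- list(model = object)
  if (!is.null(data)) {
    y <- as_label(data[[label]], nrow(data))
    s <- predict(object, data, type = "abps")
    out$scores <- data.frame(label = y, abps = s)
    out$by_class <- tapply(s, y, function(v)
      c(mean = mean(v), sd = stats::sd(v)))
    out$auroc <- auroc(s, y == "doped")
    out$bands <- table(band = classify_band(s), label = y)
  }
  class(out) <- "summary.abps_model"
  out
}

#' @export
print.summary.abps_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$scores)) {
    cat("\nScore summary by class:\n")
    print(do.call(rbind, x$by_class))
    cat("\nAUROC (doped vs control):", format(x$auroc, digits = 4), "\n")
    cat("\nBand counts:\n")
    print(x$bands)
  }
  invisible(x)
}

#' @export
plot.abps_model <- function(x, data = NULL, label = "label", ...) {
  if (is.null(data))
    stop("supply a labeled cohort to plot score distributions")
  y <- as_label(data[[label]], nrow(data))
  s <- predict(x, data, type = "abps")
  dc <- stats::density(s[y == "control"])
  dd <- stats::density(s[y == "doped"])
  graphics::plot(dc, col = "steelblue", lwd = 2,
                 xlim = range(dc$x, dd$x), ylim = range(0, dc$y, dd$y),
                 main = "Calibrated ABPS score distribution",
                 xlab = "ABPS score")
  graphics::lines(dd, col = "firebrick", lwd = 2)
  graphics::abline(v = c(0, 1), lty = 2, col = "grey40")
  graphics::legend("topleft", c("control", "doped"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

# Rank-statistic AUROC (Mann-Whitney); pROC is used as the independent
# check in the test suite.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
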