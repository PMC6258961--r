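# JSON persistence for trained models. Doubles are written at full IEEE
# precision (jsonlite digits = NA) so a save/load round trip reproduces
# scores bit-identically. Marker order is canonicalized on load.

MODEL_SCHEMA <- "bloodscore-model/1"

#' Save or load a trained ABPS model
#'
#' Models are stored as schema-versioned JSON holding every component at
#' full floating-point precision: the naive Bayes training samples and
#' bandwidths, the SVM support vectors, dual coefficients and intercept,
#' the component standardization constants, the calibration map, the
#' marker ranges, and training metadata. Loading a file whose schema
#' version does not match is a hard error.
#'
#' @param model A trained `abps_model`.
#' @param path File path (`.json`).
#' @return `save_abps_model()` returns `path` invisibly;
#'   `load_abps_model()` returns the restored `abps_model`.
#' @export
save_abps_model <- function(model, path) {
  stopifnot(inherits(model, "abps_model"))
  nb <- model$nb
  obj <- list(
    schema = MODEL_SCHEMA,
    markers = model$markers,
    nb = list(
      log_prior_odds = nb$log_prior_odds,
      markers = nb$markers,
      densities = lapply(nb$densities, function(cl)
        lapply(cl, function(d) list(sample = d$sample, bw = d$bw)))
    ),
    svm = model$svm[c("markers", "coef", "intercept", "width", "C",
                      "center", "scale")],
    svm_sv = as.data.frame(model$svm$sv),
    component_center = as.list(model$component_center),
    component_scale = as.list(model$component_scale),
    calibration = if (!is.null(model$calibration)) list(
      spec = list(name = model$calibration$spec$name,
                  mean = model$calibration$spec$mean,
                  sd = model$calibration$spec$sd,
                  quantile_p = model$calibration$spec$quantiles$p,
                  quantile_q = model$calibration$spec$quantiles$q),
      knots_x = model$calibration$knots_x,
      knots_y = model$calibration$knots_y),
    ranges = unclass(model$ranges),
    meta = list(n_control = model$n_control, n_doped = model$n_doped,
                seed = model$seed, version = model$version)
  )
  # digits = I(17): full IEEE-754 round-trip precision (significant digits)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_abps_model
#' @export
load_abps_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e)))
  if (!identical(obj$schema, MODEL_SCHEMA))
    stop("model schema mismatch: expected ", MODEL_SCHEMA, ", found ",
         if (is.null(obj$schema)) "none" else obj$schema)

  ord <- .MARKERS  # canonical order, whatever order the file uses
  dens <- lapply(obj$nb$densities, function(cl) {
    out <- lapply(cl[ord], function(d) list(sample = as.numeric(d$sample),
                                            bw = as.numeric(d$bw)))
    names(out) <- ord
    out
  })
  nb <- structure(list(densities = dens,
                       log_prior_odds = as.numeric(obj$nb$log_prior_odds),
                       markers = ord),
                  class = "nb_model")

  sv <- as.matrix(obj$svm_sv)
  perm <- match(ord, obj$svm$markers)
  if (anyNA(perm)) stop("model file misses marker columns in SVM block")
  svm <- structure(list(markers = ord,
                        sv = sv[, perm, drop = FALSE],
                        coef = as.numeric(obj$svm$coef),
                        intercept = as.numeric(obj$svm$intercept),
                        width = as.numeric(obj$svm$width),
                        C = as.numeric(obj$svm$C),
                        center = as.numeric(obj$svm$center)[perm],
                        scale = as.numeric(obj$svm$scale)[perm]),
                   class = "svm_model")

  cal <- NULL
  if (!is.null(obj$calibration) && length(obj$calibration)) {
    qp <- as.numeric(obj$calibration$spec$quantile_p)
    spec <- reference_spec(obj$calibration$spec$name,
                           mean = as.numeric(obj$calibration$spec$mean),
                           sd = as.numeric(obj$calibration$spec$sd),
                           quantiles = data.frame(
                             p = qp,
                             q = as.numeric(obj$calibration$spec$quantile_q)))
    spec$name <- obj$calibration$spec$name
    cal <- structure(list(spec = spec,
                          knots_x = as.numeric(obj$calibration$knots_x),
                          knots_y = as.numeric(obj$calibration$knots_y)),
                     class = "abps_calibration")
  }

  ranges <- do.call(marker_ranges, lapply(obj$ranges[ord], as.numeric))
  structure(list(nb = nb, svm = svm,
                 component_center = unlist(obj$component_center),
                 component_scale = unlist(obj$component_scale),
                 calibration = cal, ranges = ranges,
                 n_control = obj$meta$n_control,
                 n_doped = obj$meta$n_doped,
                 seed = obj$meta$seed, markers = ord,
                 version = obj$meta$version),
            class = "abps_model")
}
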