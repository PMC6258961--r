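# Soft-margin RBF SVM component. The quadratic program is solved by
# kernlab::ksvm; the solution (support vectors, signed dual coefficients,
# intercept) is extracted into a plain structure so that decision values
# are computed by package code and the model serializes to JSON.

#' Train the SVM component
#'
#' Fits a soft-margin SVM with Gaussian (RBF) kernel
#' `k(u, v) = exp(-||u - v||^2 / (2 w^2))` in standardized marker space.
#' The raw SVM score of a profile is the signed decision-function value
#' (not the hard class label), oriented so that doped profiles score
#' positive.
#'
#' @param x Marker matrix or data frame (clipped), one row per sample.
#' @param y Class labels (`control` / `doped`).
#' @param C Soft-margin cost, positive. Default 1.
#' @param width Kernel width `w`; `"auto"` (default) uses the median
#'   pairwise Euclidean distance between standardized training points.
#' @param center,scale Optional per-marker standardization constants;
#'   computed from the training data when `NULL`. Supplying them fixes the
#'   feature space, e.g. to make duplicated training data (with `C` scaled
#'   by the duplication factor) reproduce the original decision function.
#' @param seed Optional RNG seed set before the solver runs.
#' @return An object of class `svm_model` with elements `sv` (support
#'   vectors, standardized space), `coef` (signed dual coefficients),
#'   `intercept`, `width`, `C`, `center`, `scale`, `markers`.
#' @export
train_svm <- function(x, y, C = 1, width = "auto",
                      center = NULL, scale = NULL, seed = NULL) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a positive number")
  x <- as_feature_matrix(x)
  y <- as_label(y, nrow(x))

  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2L, stats::sd)
  if (any(scale == 0))
    stop("zero-variance marker: ",
         paste(colnames(x)[scale == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  if (identical(width, "auto")) {
    d <- stats::dist(xs)
    width <- stats::median(d[d > 0])
  }
  if (!is.finite(width) || width <= 0) stop("kernel width must be positive")
  sigma <- 1 / (2 * width^2)  # kernlab rbfdot: exp(-sigma ||u-v||^2)

  if (!is.null(seed)) set.seed(seed)
  fit <- kernlab::ksvm(xs, y, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = sigma), C = C,
                       scaled = FALSE, tol = 1e-7)
  sv_idx <- unlist(kernlab::alphaindex(fit))
  model <- structure(list(
    markers = colnames(x),
    sv = xs[sv_idx, , drop = FALSE],
    coef = unname(unlist(kernlab::coef(fit))),
    intercept = -kernlab::b(fit),
    width = width, C = C,
    center = unname(center), scale = unname(scale)
  ), class = "svm_model")

  # orient so doped scores positive (kernlab's internal sign depends on
  # label ordering)
  d <- svm_decision(model, x)
  if (mean(d[y == "doped"]) < mean(d[y == "control"])) {
    model$coef <- -model$coef
    model$intercept <- -model$intercept
  }
  model
}

#' Signed SVM decision values
#'
#' @param model An `svm_model` from [train_svm()].
#' @param x Marker matrix or data frame (clipped).
#' @return Numeric vector of decision-function values, positive favouring
#'   doped.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  x <- as_feature_matrix(x, model$markers)
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  rbf_decision(xs, model$sv, model$coef, model$width) + model$intercept
}

# Kernel rows and their contraction with the dual coefficients use only
# elementwise ops and row-wise sums (no BLAS matrix products), so each
# score's rounding is independent of the row's position in the batch:
# scoring is bit-identical under row permutation. Chunked over rows to
# bound memory on large cohorts.
rbf_decision <- function(a, sv, coef, width, chunk = 4000L) {
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(a))
    d2 <- 0
    for (k in seq_len(ncol(a)))
      d2 <- d2 + (outer(a[i, k], sv[, k], "-"))^2
    K <- exp(-d2 / (2 * width^2))
    out[i] <- rowSums(K * rep(coef, each = length(i)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
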