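# Gaussian-KDE naive Bayes over the seven markers.
#
# Each class-conditional marker density is a Gaussian kernel density
# estimate with Silverman (nrd0) bandwidth, evaluated exactly by summation
# over the stored training sample (log-sum-exp for tail stability). The
# naive (independence) combination across markers gives the class log
# likelihood; the raw NB score is the doped-vs-control log odds.

#' Train the kernel-density naive Bayes component
#'
#' Fits, per marker and per class, a one-dimensional Gaussian kernel
#' density estimate (Silverman's rule-of-thumb bandwidth) on the training
#' sample. The raw NB score of a profile is
#' `sum_m [log f_doped(x_m) - log f_control(x_m)] + log(prior odds)`.
#'
#' @param x Numeric matrix or data frame of clipped marker values, one row
#'   per sample, columns the seven markers (extra columns ignored).
#' @param y Class labels, coercible to a factor with levels `control` and
#'   `doped`.
#' @param priors Named class priors, default equal (`c(control = .5, doped
#'   = .5)`): training prevalence is a sampling artifact, not a population
#'   prior.
#' @param min_per_class Minimum training samples per class (default 10);
#'   may be lowered for controlled toy problems.
#' @return An object of class `nb_model` holding, per class and marker, the
#'   training sample and bandwidth, plus the log prior odds.
#' @export
train_naive_bayes <- function(x, y, priors = c(control = 0.5, doped = 0.5),
                              min_per_class = 10) {
  x <- as_feature_matrix(x)
  y <- as_label(y, nrow(x))
  if (any(table(y) < min_per_class))
    stop("each class needs at least ", min_per_class, " samples")
  if (!all(c("control", "doped") %in% names(priors)) ||
      any(priors <= 0))
    stop("priors must be positive and named control/doped")
  priors <- priors / sum(priors)

  dens <- list()
  for (cl in c("control", "doped")) {
    xc <- x[y == cl, , drop = FALSE]
    dens[[cl]] <- lapply(colnames(x), function(m) {
      v <- xc[, m]
      if (stats::sd(v) == 0)
        stop("zero-variance marker within class ", cl, ": ", m)
      list(sample = v, bw = stats::bw.nrd0(v))
    })
    names(dens[[cl]]) <- colnames(x)
  }
  structure(list(densities = dens,
                 log_prior_odds = log(priors[["doped"]]) -
                   log(priors[["control"]]),
                 markers = colnames(x)),
            class = "nb_model")
}

# Exact KDE log density via log-sum-exp, chunked over evaluation points so
# that large cohorts (1e5 profiles) stay within memory.
kde_log_density <- function(x_eval, x_train, bw, chunk = 4000L) {
  n <- length(x_train)
  out <- numeric(length(x_eval))
  const <- -log(bw) - 0.5 * log(2 * pi) - log(n)
  for (s in seq(1L, length(x_eval), by = chunk)) {
    i <- s:min(s + chunk - 1L, length(x_eval))
    z <- outer(x_eval[i], x_train, "-") / bw
    lk <- -0.5 * z * z
    mx <- apply(lk, 1L, max)
    out[i] <- mx + log(rowSums(exp(lk - mx))) + const
  }
  out
}

#' Raw naive Bayes score (doped-vs-control log odds)
#'
#' @param model An `nb_model` from [train_naive_bayes()].
#' @param x Marker matrix or data frame (clipped), as in training.
#' @return Numeric vector of log-odds scores, positive favouring doped.
#' @export
nb_score <- function(model, x) {
  stopifnot(inherits(model, "nb_model"))
  x <- as_feature_matrix(x, model$markers)
  s <- rep(model$log_prior_odds, nrow(x))
  for (m in model$markers) {
    dd <- model$densities$doped[[m]]
    dc <- model$densities$control[[m]]
    s <- s + kde_log_density(x[, m], dd$sample, dd$bw) -
      kde_log_density(x[, m], dc$sample, dc$bw)
  }
  unname(s)
}

# Numeric check that each stored KDE integrates to one (quadrature over a
# wide support); used by validation and the test suite.
nb_density_mass <- function(model, n_grid = 2048L) {
  sapply(c("control", "doped"), function(cl)
    sapply(model$markers, function(m) {
      d <- model$densities[[cl]][[m]]
      lo <- min(d$sample) - 8 * d$bw
      hi <- max(d$sample) + 8 * d$bw
      g <- seq(lo, hi, length.out = n_grid)
      f <- exp(kde_log_density(g, d$sample, d$bw))
      sum((f[-1] + f[-n_grid]) / 2 * diff(g))
    }))
}

# Coerce profiles to a numeric feature matrix. With `markers` given, the
# named columns are selected (canonical order); otherwise all columns are
# used as features (the components work for any feature set, not just the
# seven markers, which the toy fixtures in the test suite rely on).
as_feature_matrix <- function(x, markers = NULL) {
  if (is.data.frame(x)) {
    if (is.null(markers))
      markers <- if (all(.MARKERS %in% names(x))) .MARKERS else
        names(x)[vapply(x, is.numeric, logical(1))]
    missing <- setdiff(markers, names(x))
    if (length(missing))
      stop("missing marker: ", paste(missing, collapse = ", "))
    x <- as.matrix(x[markers])
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
      colnames(x) <- paste0("V", seq_len(ncol(x)))
    if (!is.null(markers)) {
      missing <- setdiff(markers, colnames(x))
      if (length(missing))
        stop("missing marker: ", paste(missing, collapse = ", "))
      x <- x[, markers, drop = FALSE]
    }
  }
  storage.mode(x) <- "double"
  x
}

as_label <- function(y, n) {
  y <- factor(as.character(y), levels = c("control", "doped"))
  if (anyNA(y)) stop("labels must be 'control' or 'doped'")
  if (length(y) != n) stop("label length does not match rows")
  y
}
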