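# Independent oracles and fixture builders for the test suite. These
# recompute results from first principles (direct kernel summation, KKT
# active-set enumeration) and deliberately share no code with the package
# internals they check.

# Silverman rule-of-thumb bandwidth, written out from the formula
# h = 0.9 * min(sd, IQR/1.34) * n^(-1/5).
silverman_bw <- function(x) {
  s <- sd(x)
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  0.9 * min(s, iqr / 1.34) * length(x)^(-1 / 5)
}

# Brute-force KDE naive Bayes log odds: per feature, mean of Gaussian
# kernels by direct summation; naive product across features.
nb_oracle <- function(x_train, y, x_eval, prior_doped = 0.5) {
  feats <- colnames(x_train)
  s <- rep(log(prior_doped / (1 - prior_doped)), nrow(x_eval))
  for (m in feats) {
    for (cl in c("doped", "control")) {
      v <- x_train[y == cl, m]
      h <- silverman_bw(v)
      f <- vapply(x_eval[, m],
                  function(z) mean(dnorm(z, mean = v, sd = h)), numeric(1))
      s <- s + if (cl == "doped") log(f) else -log(f)
    }
  }
  s
}

# Exact soft-margin SVM by KKT active-set enumeration: every point is
# assigned to {alpha = 0, alpha = C, free}; the linear KKT system of each
# assignment is solved and feasibility checked. Returns decision values at
# the training points. Only assignments with at least one free SV are
# considered (the test problems are generic).
svm_kkt_oracle <- function(X, ysign, C, width) {
  n <- nrow(X)
  K <- exp(-as.matrix(dist(X))^2 / (2 * width^2))
  states <- expand.grid(rep(list(0:2), n))
  for (s in seq_len(nrow(states))) {
    st <- unlist(states[s, ])
    Fr <- which(st == 2); B <- which(st == 1); Z <- which(st == 0)
    if (!length(Fr)) next
    beta <- numeric(n); beta[B] <- C * ysign[B]
    A <- rbind(cbind(K[Fr, Fr, drop = FALSE], 1),
               c(rep(1, length(Fr)), 0))
    rhs <- c(ysign[Fr] - K[Fr, B, drop = FALSE] %*% beta[B], -sum(beta[B]))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    beta[Fr] <- sol[seq_along(Fr)]
    b <- sol[length(sol)]
    alpha <- beta * ysign
    if (any(alpha[Fr] <= 1e-9) || any(alpha[Fr] >= C - 1e-9)) next
    f <- drop(K %*% beta) + b
    if (length(Z) && any(ysign[Z] * f[Z] < 1 - 1e-7)) next
    if (length(B) && any(ysign[B] * f[B] > 1 + 1e-7)) next
    return(unname(f))
  }
  stop("no feasible KKT candidate with a free support vector")
}

# Random but physiologically centred profiles, possibly out of range, for
# property tests.
random_profiles <- function(n) {
  data.frame(
    HCT = runif(n, 20, 70),
    HGB = runif(n, 8, 25),
    MCH = runif(n, 18, 42),
    MCHC = runif(n, 25, 42),
    MCV = runif(n, 60, 120),
    RBC = runif(n, 2.5, 8),
    RETP = runif(n, 0.02, 5)
  )
}

# A small labeled toy cohort (two features) with class separation, used by
# the oracle-equivalence tests.
toy_cohort_8 <- function() {
  x <- matrix(c(1.0, 2.0,
                1.2, 2.2,
                0.8, 1.9,
                1.1, 2.4,
                2.0, 3.1,
                2.2, 2.9,
                1.9, 3.3,
                2.4, 3.0), 8, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  list(x = x, y = rep(c("control", "doped"), each = 4))
}

default_model_cache <- local({
  model <- NULL
  function() {
    if (is.null(model))
      model <<- suppressWarnings(
        abps_fit(simulate_cohort(cohort_spec(seed = 1)), seed = 1))
    model
  }
})
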