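# Synthetic athlete cohorts. Clean profiles are drawn from a multivariate
# lognormal over the four primary markers (HGB, RBC, MCV, RETP), per sex;
# the derived red-cell indices follow the hematological identities
#   HCT [%]   = MCV [fL] * RBC [10^6/uL] / 10
#   MCH [pg]  = HGB [g/dL] / RBC * 10
#   MCHC [g/dL] = HGB / HCT * 100
# up to small bounded multiplicative noise, so generated profiles stay
# physiologically coherent. Doped profiles apply rhEPO-style shifts: HGB
# and RBC elevated; RETP elevated during stimulation ("ON phase") or
# suppressed after withdrawal ("OFF phase").

#' Specification of a synthetic athlete cohort
#'
#' Defaults emulate the size of the training database behind the original
#' score (402 clean controls and 189 doped profiles, 591 in total) with
#' physiological marker levels; all effect sizes are configuration, not
#' claims about real athletes.
#'
#' @param n_control,n_doped Cohort sizes; defaults 402 and 189.
#' @param seed Optional integer seed; same spec + same seed gives a
#'   bit-identical cohort.
#' @param sex_ratio Fraction of male profiles, default 0.5.
#' @param log_mean_male,log_mean_female Named log-scale means of the
#'   primary markers `HGB`, `RBC`, `MCV`, `RETP` (natural units g/dL,
#'   10^6/uL, fL, \%).
#' @param log_sd Named log-scale standard deviations of the primaries.
#' @param log_corr 4x4 correlation matrix of the log primaries (order HGB,
#'   RBC, MCV, RETP); must be symmetric positive definite.
#' @param doped_shift Named multiplicative shifts applied to doped
#'   profiles' `HGB`, `RBC`, `MCV` medians.
#' @param retp_on,retp_off Multiplicative RETP shift for ON-phase
#'   (stimulated, elevated) and OFF-phase (withdrawn, suppressed) doped
#'   profiles.
#' @param off_phase_fraction Fraction of doped profiles in OFF phase,
#'   default 0.5.
#' @param variance_inflation Factor multiplying the doped log-scale
#'   covariance, default 1.3.
#' @param derived_noise_sd Named log-scale noise sd for the derived
#'   markers `HCT`, `MCH`, `MCHC`; each draw is truncated at 4 sd so the
#'   identity deviations stay bounded.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 402, n_doped = 189, seed = NULL,
                        sex_ratio = 0.5,
                        log_mean_male = log(c(HGB = 14.5, RBC = 5.0,
                                              MCV = 90, RETP = 1.0)),
                        log_mean_female = log(c(HGB = 13.2, RBC = 4.6,
                                                MCV = 90, RETP = 1.0)),
                        log_sd = c(HGB = 0.055, RBC = 0.06,
                                   MCV = 0.045, RETP = 0.35),
                        log_corr = default_log_corr(),
                        doped_shift = c(HGB = 1.10, RBC = 1.07, MCV = 1.00),
                        retp_on = 2.2, retp_off = 0.35,
                        off_phase_fraction = 0.5,
                        variance_inflation = 1.3,
                        derived_noise_sd = c(HCT = 0.012, MCH = 0.010,
                                             MCHC = 0.008)) {
  if (n_control < 0 || n_doped < 0) stop("cohort sizes must be >= 0")
  log_corr <- as.matrix(log_corr)
  if (!isSymmetric(log_corr) || any(eigen(log_corr, symmetric = TRUE,
                                          only.values = TRUE)$values <= 0))
    stop("log_corr must be symmetric positive definite")
  structure(list(n_control = n_control, n_doped = n_doped, seed = seed,
                 sex_ratio = sex_ratio,
                 log_mean_male = log_mean_male,
                 log_mean_female = log_mean_female,
                 log_sd = log_sd, log_corr = log_corr,
                 doped_shift = doped_shift,
                 retp_on = retp_on, retp_off = retp_off,
                 off_phase_fraction = off_phase_fraction,
                 variance_inflation = variance_inflation,
                 derived_noise_sd = derived_noise_sd),
            class = "cohort_spec")
}

default_log_corr <- function() {
  p <- c("HGB", "RBC", "MCV", "RETP")
  r <- diag(4)
  dimnames(r) <- list(p, p)
  r["HGB", "RBC"] <- r["RBC", "HGB"] <- 0.65
  r["RBC", "MCV"] <- r["MCV", "RBC"] <- -0.35
  r["HGB", "MCV"] <- r["MCV", "HGB"] <- 0.10
  r
}

#' Simulate a synthetic athlete cohort
#'
#' Draws `n_control` clean and `n_doped` rhEPO-style doped blood profiles
#' according to a [cohort_spec()]. Labels are attached in a `label` column
#' (`control` / `doped`); doped rows additionally carry their `phase`
#' (`on` / `off`).
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `sample_id`, the seven markers, `sex`,
#'   `label`, `phase`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_control = 20, n_doped = 10,
#'                                       seed = 1))
#' table(cohort$label)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(spec$seed)
  }
  ctrl <- draw_profiles(spec, spec$n_control, doped = FALSE)
  dop <- draw_profiles(spec, spec$n_doped, doped = TRUE)
  out <- rbind(ctrl, dop)
  if (nrow(out))
    out$sample_id <- sprintf("S%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("sample_id", .MARKERS, "sex", "label", "phase")]
}

draw_profiles <- function(spec, n, doped) {
  if (n == 0L)
    return(data.frame(sample_id = character(), HCT = numeric(),
                      HGB = numeric(), MCH = numeric(), MCHC = numeric(),
                      MCV = numeric(), RBC = numeric(), RETP = numeric(),
                      sex = character(), label = character(),
                      phase = character(), stringsAsFactors = FALSE))
  p <- c("HGB", "RBC", "MCV", "RETP")
  sd <- spec$log_sd[p]
  cov <- diag(sd) %*% spec$log_corr[p, p] %*% diag(sd)
  if (doped) cov <- cov * spec$variance_inflation

  male <- stats::runif(n) < spec$sex_ratio
  mu <- matrix(0, n, 4, dimnames = list(NULL, p))
  if (any(male))
    mu[male, ] <- matrix(spec$log_mean_male[p], sum(male), 4, byrow = TRUE)
  if (any(!male))
    mu[!male, ] <- matrix(spec$log_mean_female[p], sum(!male), 4,
                          byrow = TRUE)

  phase <- rep(NA_character_, n)
  if (doped) {
    shift <- log(spec$doped_shift[c("HGB", "RBC", "MCV")])
    mu[, c("HGB", "RBC", "MCV")] <-
      sweep(mu[, c("HGB", "RBC", "MCV"), drop = FALSE], 2L, shift, "+")
    phase <- ifelse(stats::runif(n) < spec$off_phase_fraction, "off", "on")
    mu[, "RETP"] <- mu[, "RETP"] +
      log(ifelse(phase == "off", spec$retp_off, spec$retp_on))
  }

  z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = cov)
  if (n == 1L) z <- matrix(z, nrow = 1L)
  prim <- exp(mu + z)
  colnames(prim) <- p

  ns <- spec$derived_noise_sd
  trunc_noise <- function(s) {
    e <- stats::rnorm(n, 0, s)
    pmin(4 * s, pmax(-4 * s, e))
  }
  HCT <- prim[, "MCV"] * prim[, "RBC"] / 10 * exp(trunc_noise(ns[["HCT"]]))
  MCH <- prim[, "HGB"] / prim[, "RBC"] * 10 * exp(trunc_noise(ns[["MCH"]]))
  MCHC <- prim[, "HGB"] / HCT * 100 * exp(trunc_noise(ns[["MCHC"]]))

  data.frame(sample_id = NA_character_,
             HCT = HCT, HGB = prim[, "HGB"], MCH = MCH, MCHC = MCHC,
             MCV = prim[, "MCV"], RBC = prim[, "RBC"],
             RETP = prim[, "RETP"],
             sex = ifelse(male, "male", "female"),
             label = if (doped) "doped" else "control",
             phase = phase, stringsAsFactors = FALSE)
}

#' Deterministic example fixtures
#'
#' Two small, fully reproducible profile sets in the style of anti-doping
#' example data:
#' \describe{
#'   \item{`control13`}{13 plausible clean profiles (internal fixed seed).}
#'   \item{`doping13`}{a longitudinal series of 13 samples from one female
#'     athlete whose hemoglobin rises while reticulocytes collapse
#'     (OFF-phase pattern), so later samples score in the suspicion or
#'     abnormal band. Synthetic values; not measurements of any real
#'     athlete.}
#' }
#'
#' @param name `"control13"` or `"doping13"`.
#' @return Data frame of 13 profiles; `doping13` carries a `date` column
#'   with non-decreasing sample dates.
#' @export
make_fixture <- function(name = c("control13", "doping13")) {
  name <- match.arg(name)
  if (name == "control13") {
    out <- simulate_cohort(cohort_spec(n_control = 13, n_doped = 0,
                                       seed = 1303))
    out$sample_id <- sprintf("C%02d", 1:13)
    out$label <- NULL; out$phase <- NULL
    return(out)
  }
  # doping13: deterministic longitudinal series, no RNG
  k <- 0:12
  HGB <- round(13.1 + 0.22 * k + 0.15 * sin(k), 1)       # 13.1 -> ~15.8
  RETP <- round(pmax(0.15, 1.1 - 0.08 * k - 0.25 * (k >= 8)), 2)
  RBC <- round(4.55 + 0.05 * k, 2)
  MCV <- round(rep(89, 13) + 0.2 * sin(2 * k), 1)
  HCT <- round(MCV * RBC / 10, 1)
  MCH <- round(HGB / RBC * 10, 1)
  MCHC <- round(HGB / HCT * 100, 1)
  data.frame(sample_id = sprintf("D%02d", 1:13),
             date = as.Date("2001-03-01") + 182 * k,
             HCT = HCT, HGB = HGB, MCH = MCH, MCHC = MCHC, MCV = MCV,
             RBC = RBC, RETP = RETP, sex = "female",
             stringsAsFactors = FALSE)
}
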