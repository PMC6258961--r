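#' OFF-score
#'
#' The OFF-score (also called OFF-hr score or stimulation index) is an
#' indirect marker of blood doping that combines hemoglobin with the
#' reticulocyte percentage:
#'
#' \deqn{\mathrm{OFF} = \mathrm{HGB} \times 10 - 60 \times \sqrt{}\mathrm{RETP}}{
#' OFF = HGB*10 - 60*RETP}
#'
#' where HGB is in g/dL (the factor 10 converts to g/L internally) and RETP
#' in percent. Erythropoietin withdrawal ("OFF phase") leaves hemoglobin
#' high while reticulocyte production collapses, which drives the score up.
#' Typical values lie between 85 and 95; in the worst-case population (male
#' athletes at low altitude) values over 133 are considered evidence of
#' doping.
#'
#' The score is computed on raw values; the range clipping used by the ABPS
#' ensemble does not apply here. A warning is emitted when the inputs look
#' like the wrong unit (HGB > 30 suggests g/L; RETP > 25 suggests an
#' absolute count).
#'
#' @param HGB Hemoglobin concentration(s), g/dL. Alternatively a data frame
#'   holding `HGB` and `RETP` columns (e.g. from [read_profiles()]).
#' @param RETP Reticulocyte percentage(s). Ignored when `HGB` is a data
#'   frame.
#' @param warn_units Emit unit-plausibility warnings? Default `TRUE`.
#' @return Numeric vector of OFF-scores (unitless).
#' @examples
#' off_score(14.0, 0.5)   # 110
#' off_score(19.3, 1.0)   # 133, the worst-case doping threshold
#' @seealso [flag_off_score()]
#' @export
off_score <- function(HGB, RETP = NULL, warn_units = TRUE) {
  if (is.data.frame(HGB)) {
    df <- HGB
    nm <- toupper(names(df))
    h <- match("HGB", nm); r <- match("RETP", nm)
    if (is.na(h) || is.na(r))
      stop("data frame input must have HGB and RETP columns")
    HGB <- as.numeric(df[[h]]); RETP <- as.numeric(df[[r]])
  }
  if (length(HGB) != length(RETP))
    stop("HGB and RETP must have the same length")
  if (any(!is.finite(HGB)) || any(!is.finite(RETP)))
    stop("HGB and RETP must be finite")
  if (any(HGB <= 0) || any(RETP < 0))
    stop("HGB must be positive and RETP non-negative")
  if (warn_units) {
    if (any(HGB > 30))
      warning("HGB > 30: value(s) look like g/L, expected g/dL", call. = FALSE)
    if (any(RETP > 25))
      warning("RETP > 25: value(s) look like an absolute count, ",
              "expected percent", call. = FALSE)
  }
  HGB * 10 - 60 * RETP
}

#' Flag OFF-scores above a doping threshold
#'
#' @param score Numeric OFF-score(s).
#' @param threshold Decision threshold; the default 133 is the published
#'   worst-case value (male athlete at low altitude). Thresholds for other
#'   populations may be supplied instead.
#' @return Logical: `TRUE` where the score strictly exceeds the threshold.
#' @examples
#' flag_off_score(c(90, 133, 134))  # FALSE FALSE TRUE
#' @export
flag_off_score <- function(score, threshold = 133) {
  if (any(!is.finite(score))) stop("score must be finite")
  score > threshold
}
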