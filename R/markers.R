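#' The seven hematological markers
#'
#' Canonical names and units of the seven markers the ABPS combines:
#' \describe{
#'   \item{HCT}{haematocrit, \%}
#'   \item{HGB}{hemoglobin concentration, g/dL}
#'   \item{MCH}{mean corpuscular hemoglobin, pg}
#'   \item{MCHC}{mean corpuscular hemoglobin concentration, g/dL}
#'   \item{MCV}{mean corpuscular volume, fL}
#'   \item{RBC}{red blood cell count, 10^6/uL}
#'   \item{RETP}{reticulocytes percent, \%}
#' }
#'
#' @return Character vector of the seven marker names, in canonical order.
#' @export
abps_markers <- function() {
  c("HCT", "HGB", "MCH", "MCHC", "MCV", "RBC", "RETP")
}

.MARKERS <- c("HCT", "HGB", "MCH", "MCHC", "MCV", "RBC", "RETP")

#' Per-marker clipping ranges
#'
#' The scoring algorithm restricts each marker to a physiological range; a
#' value outside the range is replaced by the nearest bound before scoring.
#' The hemoglobin bounds (12.9 and 18.2 g/dL) are fixed by the method; the
#' other six defaults are wide physiological ranges and can be overridden.
#'
#' @param HCT,HGB,MCH,MCHC,MCV,RBC,RETP Numeric `c(lower, upper)` pairs, in
#'   the marker's unit.
#' @return An object of class `marker_ranges`: a named list of
#'   `c(lower, upper)` pairs, one per marker.
#' @examples
#' r <- marker_ranges()
#' r$HGB   # c(12.9, 18.2)
#' @export
marker_ranges <- function(HCT = c(35, 55), HGB = c(12.9, 18.2),
                          MCH = c(24, 36), MCHC = c(30, 38),
                          MCV = c(75, 105), RBC = c(3.5, 6.5),
                          RETP = c(0.1, 3.0)) {
  r <- list(HCT = HCT, HGB = HGB, MCH = MCH, MCHC = MCHC,
            MCV = MCV, RBC = RBC, RETP = RETP)
  for (m in .MARKERS) {
    v <- as.numeric(r[[m]])
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop("marker_ranges: ", m, " must be c(lower, upper) with lower < upper")
    r[[m]] <- v
  }
  structure(r, class = "marker_ranges")
}

#' Validate blood profiles
#'
#' Checks that a data frame carries the seven marker columns and that every
#' marker value is a finite, strictly positive number.
#'
#' @param profiles A data frame with (at least) the seven marker columns.
#' @return Invisibly, `profiles`; stops with an informative error otherwise.
#' @export
validate_profiles <- function(profiles) {
  if (!is.data.frame(profiles))
    stop("profiles must be a data frame")
  missing <- setdiff(.MARKERS, names(profiles))
  if (length(missing))
    stop("missing marker: ", paste(missing, collapse = ", "))
  for (m in .MARKERS) {
    v <- profiles[[m]]
    if (!is.numeric(v))
      stop("marker ", m, " is not numeric")
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop("marker ", m, " has non-finite or non-positive values in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(profiles)
}

#' Clip marker values to their allowed ranges
#'
#' Any marker value outside its allowed range is replaced by the nearest
#' bound (for example, an HGB of 12.0 g/dL becomes 12.9 and an HGB of 19.0
#' becomes 18.2). A warning is emitted whenever a value is modified, and the
#' modifications are recorded as a data frame of clip events attached as the
#' `"clip_events"` attribute (columns `row`, `marker`, `original`,
#' `clipped`).
#'
#' Clipping is applied to the inputs of the ABPS ensemble only; the
#' OFF-score is computed on raw values.
#'
#' @param profiles A validated data frame of blood profiles.
#' @param ranges A [marker_ranges()] object.
#' @param warn Emit a warning when any value is clipped? Default `TRUE`.
#' @return `profiles` with markers clipped, plus a `"clip_events"` attribute.
#' @examples
#' p <- data.frame(HCT = 43, HGB = 12.0, MCH = 29, MCHC = 32.5,
#'                 MCV = 89, RBC = 4.8, RETP = 1.1)
#' clipped <- suppressWarnings(clip_profiles(p))
#' clipped$HGB  # 12.9
#' @export
clip_profiles <- function(profiles, ranges = marker_ranges(), warn = TRUE) {
  validate_profiles(profiles)
  if (!inherits(ranges, "marker_ranges"))
    stop("ranges must be a marker_ranges object")
  events <- list()
  for (m in .MARKERS) {
    v <- profiles[[m]]
    lo <- ranges[[m]][1]; hi <- ranges[[m]][2]
    w <- pmin(hi, pmax(lo, v))
    mod <- which(w != v)
    if (length(mod))
      events[[m]] <- data.frame(row = mod, marker = m,
                                original = v[mod], clipped = w[mod])
    profiles[[m]] <- w
  }
  events <- if (length(events)) do.call(rbind, c(events, make.row.names = FALSE))
            else data.frame(row = integer(), marker = character(),
                            original = numeric(), clipped = numeric())
  if (warn && nrow(events))
    warning(nrow(events), " marker value(s) outside the allowed range were ",
            "clipped (", paste(unique(events$marker), collapse = ", "), ")",
            call. = FALSE)
  attr(profiles, "clip_events") <- events
  profiles
}

#' Heuristic unit checks for blood profiles
#'
#' Flags marker values that look like they were reported in the wrong unit:
#' an HGB above 30 suggests g/L instead of g/dL, an HCT below 1 suggests a
#' fraction instead of a percentage, and a RETP above 25 suggests an
#' absolute reticulocyte count instead of a percentage.
#'
#' @param profiles A data frame with the seven marker columns.
#' @return A data frame of unit warnings with columns `row`, `marker`,
#'   `value`, `message`; zero rows when every value is plausible.
#' @examples
#' check_units(data.frame(HCT = 43, HGB = 145, MCH = 29, MCHC = 32.5,
#'                        MCV = 89, RBC = 4.8, RETP = 1.1))
#' @export
check_units <- function(profiles) {
  missing <- setdiff(.MARKERS, names(profiles))
  if (length(missing))
    stop("missing marker: ", paste(missing, collapse = ", "))
  rules <- list(
    list(marker = "HGB", test = function(v) v > 30,
         msg = "HGB > 30: value looks like g/L, expected g/dL"),
    list(marker = "HCT", test = function(v) v < 1,
         msg = "HCT < 1: value looks like a fraction, expected percent"),
    list(marker = "RETP", test = function(v) v > 25,
         msg = "RETP > 25: value looks like an absolute count, expected percent")
  )
  out <- list()
  for (r in rules) {
    v <- profiles[[r$marker]]
    bad <- which(is.finite(v) & r$test(v))
    if (length(bad))
      out[[r$marker]] <- data.frame(row = bad, marker = r$marker,
                                    value = v[bad], message = r$msg)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(row = integer(), marker = character(),
                  value = numeric(), message = character())
}
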