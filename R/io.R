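#' Read blood profiles from a CSV file
#'
#' Reads a delimited text file with a header row naming at least the seven
#' markers (matched case-insensitively, in any column order) and returns a
#' data frame in canonical column order. A `sample_id` column (or `id`) is
#' used if present, otherwise row numbers are assigned. Extra columns are
#' preserved. Rows with a missing or non-numeric marker value are dropped
#' with a per-row diagnostic; the remaining rows are still returned.
#'
#' @param file Path to a delimited text file (lines starting with `#` are
#'   ignored, so files written by [write_profiles()] read back cleanly).
#' @param sep Field separator, default `","`.
#' @param quiet Suppress the row-count message? Default `FALSE`.
#' @return A data frame with columns `sample_id`, the seven markers, and any
#'   extra input columns. Attribute `"n_rejected"` counts dropped rows.
#' @export
read_profiles <- function(file, sep = ",", quiet = FALSE) {
  raw <- tryCatch(
    utils::read.csv(file, sep = sep, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(raw) || (nrow(raw) == 0L && ncol(raw) == 0L)) {
    warning("empty file: ", file, call. = FALSE)
    return(empty_profiles())
  }
  nm <- names(raw)
  idx <- match(.MARKERS, toupper(nm))
  if (anyNA(idx))
    stop("missing marker: ", paste(.MARKERS[is.na(idx)], collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("no data rows in ", file, call. = FALSE)
    return(empty_profiles())
  }

  id_col <- match(c("sample_id", "id"), tolower(nm))
  id_col <- id_col[!is.na(id_col)][1]
  ids <- if (!is.na(id_col)) as.character(raw[[id_col]]) else
    as.character(seq_len(nrow(raw)))

  mk <- raw[idx]
  names(mk) <- .MARKERS
  bad <- rep(FALSE, nrow(raw))
  for (m in .MARKERS) {
    v <- suppressWarnings(as.numeric(as.character(mk[[m]])))
    newbad <- is.na(v) & !bad
    for (i in which(newbad))
      warning("row ", i, " (", ids[i], "): marker ", m,
              " is missing or non-numeric; row rejected", call. = FALSE)
    bad <- bad | is.na(v)
    mk[[m]] <- v
  }

  extra <- raw[setdiff(seq_along(nm), c(idx, if (!is.na(id_col)) id_col))]
  out <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), mk, extra)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message("read ", nrow(out), " profile(s) from ", file,
            if (sum(bad)) paste0(" (", sum(bad), " row(s) rejected)") else "")
  attr(out, "n_rejected") <- sum(bad)
  out
}

empty_profiles <- function() {
  out <- data.frame(sample_id = character())
  for (m in .MARKERS) out[[m]] <- numeric()
  out
}

#' Write blood profiles (or any result table) to CSV
#'
#' Writes a data frame as comma-separated text, optionally preceded by a
#' `#`-prefixed comment line (used by the CLI to record the tool version and
#' configuration hash). The file is written atomically: output goes to a
#' temporary file in the same directory which is then renamed.
#'
#' @param x A data frame.
#' @param file Output path.
#' @param comment Optional single comment line (without the leading `#`).
#' @return Invisibly, `file`.
#' @export
write_profiles <- function(x, file, comment = NULL) {
  tmp <- tempfile(tmpdir = dirname(file), fileext = ".csv.tmp")
  con <- file(tmp, open = "w", encoding = "UTF-8")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!file.rename(tmp, file)) {
    file.copy(tmp, file, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(file)
}
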