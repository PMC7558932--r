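#' Construct an inter-beat-interval series
#'
#' An IBI series is stored as a tibble with one row per interval: `beat`
#' (index), `rr` (interval length, ms) and `time` (cumulative onset time in
#' seconds, starting at 0, so `time[k] = sum(rr[seq_len(k - 1)]) / 1000`).
#' All pipeline functions take and return this shape, so stages chain with
#' the pipe.
#'
#' @param rr Numeric vector of intervals in milliseconds, chronological.
#' @param id Optional recording label, kept as the `"source_id"` attribute.
#' @return A tibble with columns `beat`, `rr`, `time`.
#' @examples
#' ibi_series(c(800, 810, 790))
#' @export
ibi_series <- function(rr, id = NULL) {
  rr <- as.numeric(rr)
  if (length(rr) == 0) stop("IBI series must contain at least one interval")
  if (anyNA(rr) || any(rr <= 0)) {
    stop("all inter-beat intervals must be positive and non-missing")
  }
  out <- tibble::tibble(
    beat = seq_along(rr),
    rr = rr,
    time = cumsum(c(0, rr[-length(rr)])) / 1000
  )
  if (!is.null(id)) attr(out, "source_id") <- id
  out
}

# total recorded duration in seconds
ibi_duration <- function(series) sum(series$rr) / 1000

check_ibi <- function(series) {
  if (!is.data.frame(series) || !all(c("rr") %in% names(series))) {
    stop("expected an IBI series tibble with an `rr` column (see ibi_series())")
  }
  if (nrow(series) == 0) stop("IBI series is empty")
  invisible(series)
}

#' Read and write plain-text IBI recordings
#'
#' One interval in milliseconds per line, chronological, blank lines
#' ignored — the interchange format of common artifact-editing tools.
#'
#' @param path File path.
#' @param id Optional recording label; defaults to the file name.
#' @return `read_ibi()` returns an IBI tibble (see [ibi_series()]);
#'   `write_ibi()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_ibi(ibi_series(c(800, 810, 790)), f)
#' read_ibi(f)
#' @export
read_ibi <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("IBI file is empty: ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop("non-numeric IBI value on line ", bad, " of ", path)
  }
  if (any(vals <= 0)) {
    bad <- keep[which(vals <= 0)[1]]
    stop("non-positive IBI value on line ", bad, " of ", path)
  }
  ibi_series(vals, id = id %||% basename(path))
}

#' @param series An IBI tibble.
#' @rdname read_ibi
#' @export
write_ibi <- function(series, path) {
  check_ibi(series)
  writeLines(format(series$rr, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
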