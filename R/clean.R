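# maximal suffix of beats whose total duration <= window seconds
ibi_suffix_window <- function(series, window, what) {
  check_ibi(series)
  if (window <= 0) stop("window must be positive")
  total <- ibi_duration(series)
  if (total < window) {
    stop(sprintf("recording (%.1f s) is shorter than the %s window (%g s)",
                 total, what, window))
  }
  suffix <- rev(cumsum(rev(series$rr))) / 1000
  out <- series[suffix <= window, , drop = FALSE]
  ibi_series(out$rr, id = attr(series, "source_id"))
}

#' Cut the artifact-detection and analysis windows
#'
#' Short-term HRV analysis uses the end of a longer acclimatisation
#' recording: artifact screening runs on the last 6 minutes and the indices
#' on the last clean 5 minutes. Both helpers return the maximal suffix of
#' beats whose total duration does not exceed `window` seconds.
#'
#' @param series An IBI tibble.
#' @param window Window length in seconds (default 360 for detection, 300
#'   for analysis).
#' @return The windowed IBI tibble (beat indices and times restart at the
#'   window).
#' @examples
#' x <- simulate_ibi(mean_rr = 800, duration = 600)
#' nrow(ibi_detection_window(x)) # 450 beats of 800 ms in 360 s
#' @export
ibi_detection_window <- function(series, window = 360) {
  ibi_suffix_window(series, window, "detection")
}

#' @rdname ibi_detection_window
#' @export
ibi_analysis_window <- function(series, window = 300) {
  ibi_suffix_window(series, window, "analysis")
}

#' Artifact percentage, rounded as reported
#'
#' Percentage of flagged beats among all beats in the detection window,
#' rounded half-up to one decimal — the convention used when reporting
#' edited data points.
#'
#' @param n_flagged,n_total Counts of flagged and total beats.
#' @return Percentage with one decimal.
#' @examples
#' artifact_percentage(17, 392) # 4.3
#' @export
artifact_percentage <- function(n_flagged, n_total) {
  stopifnot(n_total > 0, n_flagged >= 0, n_flagged <= n_total)
  round_half_up(100 * n_flagged / n_total, 1)
}

#' Detect isolated artifacts in an IBI series
#'
#' Distribution-based threshold rule on successive interval differences
#' \eqn{d_i = RR_{i+1} - RR_i}:
#' 1. compute the quartiles of the differences;
#' 2. estimate the artifact-free spread as the standard deviation of the
#'    differences inside \eqn{[Q_1, Q_3]}, divided by 0.3776 — the standard
#'    deviation of a standard normal truncated to its central 50% — giving a
#'    trimmed, normal-consistent estimate \eqn{\hat\sigma} immune to the
#'    artifacts themselves;
#' 3. threshold \eqn{T = k\hat\sigma}, default `k = 3.29` (the two-sided
#'    99.9% normal quantile);
#' 4. an interior beat is flagged when both adjacent differences exceed
#'    \eqn{T} in magnitude with opposite signs (the signature of an isolated
#'    spike or ectopic); the first and last beats use their single adjacent
#'    difference.
#'
#' Recordings with at least `disqualify_pct`% flagged beats are marked
#' disqualified.
#'
#' @param series An IBI tibble (the detection window), >= 8 intervals.
#' @param k Threshold multiplier.
#' @param trim_factor Truncation correction for the central-50% SD.
#' @param disqualify_pct Disqualification cutoff, percent (default 5).
#' @return An object of class `artifact_report`: a list with `total_points`,
#'   `flagged` (integer indices), `artifact_pct` (one decimal),
#'   `threshold` (ms) and `disqualified`. Use [glance()] for a one-row
#'   summary, [tidy()] for a per-beat table, [remove_artifacts()] to delete
#'   the flagged beats.
#' @examples
#' x <- simulate_ibi(mean_rr = 800, noise_sd = 20, duration = 360, seed = 1)
#' x <- inject_artifacts(x, "spike", positions = 100, magnitude = 300)
#' glance(detect_artifacts(x))
#' @export
detect_artifacts <- function(series, k = 3.29, trim_factor = 0.3776,
                             disqualify_pct = 5) {
  check_ibi(series)
  stopifnot(k > 0, trim_factor > 0)
  n <- nrow(series)
  if (n < 8) stop("artifact detection needs at least 8 intervals")
  d <- diff(series$rr)
  q <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  core <- d[d >= q[1] & d <= q[2]]
  sigma <- if (length(core) >= 2) sd(core) / trim_factor else 0
  if (!is.finite(sigma) || sigma == 0) {
    warning("zero variance in trimmed differences; threshold degenerate, no beats flagged")
    flagged <- integer(0)
    threshold <- 0
  } else {
    threshold <- k * sigma
    exceeds <- abs(d) > threshold
    flag <- logical(n)
    # interior: opposite-sign exceedance on both sides (isolated outlier)
    j <- which(exceeds[-length(d)] & exceeds[-1] &
                 sign(d[-length(d)]) != sign(d[-1])) + 1L
    flag[j] <- TRUE
    # boundaries: single adjacent difference
    if (exceeds[1]) flag[1] <- TRUE
    if (exceeds[length(d)]) flag[n] <- TRUE
    flagged <- which(flag)
  }
  pct <- artifact_percentage(length(flagged), n)
  structure(
    list(
      total_points = n,
      flagged = flagged,
      artifact_pct = pct,
      threshold = threshold,
      disqualified = pct >= disqualify_pct,
      disqualify_pct = disqualify_pct,
      k = k
    ),
    class = "artifact_report"
  )
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf(
    "Artifact report: %d/%d beats flagged (%.1f%%), threshold %.1f ms%s\n",
    length(x$flagged), x$total_points, x$artifact_pct, x$threshold,
    if (x$disqualified) " -- DISQUALIFIED" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.artifact_report <- function(x, ...) {
  tibble::tibble(
    total_points = x$total_points,
    n_flagged = length(x$flagged),
    artifact_pct = x$artifact_pct,
    threshold = x$threshold,
    disqualified = x$disqualified
  )
}

#' @exportS3Method generics::tidy
tidy.artifact_report <- function(x, ...) {
  tibble::tibble(
    beat = seq_len(x$total_points),
    artifact = seq_len(x$total_points) %in% x$flagged
  )
}

#' Delete flagged artifacts from an IBI series
#'
#' Flagged intervals are removed outright (no interpolation) and beat times
#' recomputed, mirroring manual deletion practice.
#'
#' @param series The IBI tibble the report was computed from.
#' @param report An [detect_artifacts()] report.
#' @return The cleaned IBI tibble.
#' @export
remove_artifacts <- function(series, report) {
  check_ibi(series)
  if (!inherits(report, "artifact_report")) stop("`report` must be an artifact_report")
  if (report$total_points != nrow(series)) {
    stop("report was not produced from this series (length mismatch)")
  }
  if (length(report$flagged) == 0) return(series)
  keep <- setdiff(seq_len(nrow(series)), report$flagged)
  if (length(keep) == 0) stop("all beats flagged; nothing left to analyse")
  ibi_series(series$rr[keep], id = attr(series, "source_id"))
}

#' One-call cleaning pipeline
#'
#' Detection window, artifact detection, deletion and analysis window in
#' one step.
#'
#' @inheritParams detect_artifacts
#' @param detection_window,analysis_window Window lengths, s.
#' @return A list with `series` (the clean analysis-window IBI tibble) and
#'   `report` (the artifact report from the detection window).
#' @examples
#' x <- simulate_ibi(mean_rr = 800, noise_sd = 15, duration = 600, seed = 7)
#' cleaned <- clean_ibi(x)
#' glance(cleaned$report)
#' @export
clean_ibi <- function(series, detection_window = 360, analysis_window = 300,
                      k = 3.29, trim_factor = 0.3776, disqualify_pct = 5) {
  if (analysis_window > detection_window) {
    stop("analysis window cannot exceed the detection window")
  }
  win <- ibi_detection_window(series, detection_window)
  report <- detect_artifacts(win, k = k, trim_factor = trim_factor,
                             disqualify_pct = disqualify_pct)
  clean <- remove_artifacts(win, report)
  list(series = ibi_analysis_window(clean, analysis_window), report = report)
}
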