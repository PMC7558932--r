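#' Time-domain HRV indices
#'
#' MeanRR, SDNN, RMSSD, pNN50 and instantaneous heart-rate summaries from a
#' cleaned IBI series. Conventions: SDNN is the sample standard deviation
#' (divisor \eqn{N-1}); RMSSD averages the squared successive differences
#' over their count (\eqn{N-1} differences); pNN50 counts strict
#' \eqn{|d_i| > 50} ms; heart rate per beat is \eqn{60000/RR_i} bpm.
#'
#' @param series An IBI tibble with at least 2 intervals.
#' @return A one-row tibble: `mean_rr`, `sdnn`, `rmssd` (ms), `pnn50` (%),
#'   `mean_hr`, `min_hr`, `max_hr` (bpm).
#' @examples
#' hrv_time_domain(ibi_series(c(800, 860, 810, 865)))
#' @export
hrv_time_domain <- function(series) {
  check_ibi(series)
  rr <- series$rr
  if (length(rr) < 2) stop("time-domain indices need at least 2 intervals")
  d <- diff(rr)
  hr <- 60000 / rr
  tibble::tibble(
    mean_rr = mean(rr),
    sdnn = sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    mean_hr = mean(hr),
    min_hr = min(hr),
    max_hr = max(hr)
  )
}

#' Poincare plot descriptors
#'
#' SD1 and SD2 of the lagged scatter plot \eqn{(RR_i, RR_{i+1})}: SD1
#' captures fast beat-to-beat variability (dispersion perpendicular to the
#' identity line), SD2 the longer-term variability along it. Computed from
#' the identities \eqn{SD1^2 = \mathrm{var}(d)/2} (sample variance of the
#' successive differences) and \eqn{SD2^2 = 2\,SDNN^2 - SD1^2} (clipped at
#' zero), so \eqn{2\,SDNN^2 = SD1^2 + SD2^2} by construction.
#'
#' @param series An IBI tibble with at least 3 intervals.
#' @return A one-row tibble with `sd1` and `sd2` (ms).
#' @examples
#' hrv_poincare(ibi_series(rep(c(780, 860), 50)))
#' @export
hrv_poincare <- function(series) {
  check_ibi(series)
  rr <- series$rr
  if (length(rr) < 3) stop("Poincare descriptors need at least 3 intervals")
  sd1 <- sqrt(var(diff(rr)) / 2)
  sd2sq <- 2 * var(rr) - sd1^2
  tibble::tibble(sd1 = sd1, sd2 = sqrt(max(0, sd2sq)))
}

#' Poincare plot
#'
#' @param series An IBI tibble.
#' @return A ggplot object: lagged scatter with the identity line.
#' @export
plot_poincare <- function(series) {
  check_ibi(series)
  rr <- series$rr
  df <- tibble::tibble(rr_i = rr[-length(rr)], rr_next = rr[-1])
  ggplot2::ggplot(df, ggplot2::aes(.data$rr_i, .data$rr_next)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(RR[i] ~ "(ms)"), y = expression(RR[i + 1] ~ "(ms)"),
                  title = "Poincare plot")
}
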