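#' Smoothness-priors detrending
#'
#' Removes the slow trend of an evenly sampled signal by penalised least
#' squares: the trend is \eqn{(I + \lambda^2 D_2^\top D_2)^{-1} z} with
#' \eqn{D_2} the \eqn{(n-2)\times n} second-difference operator, and the
#' detrended signal is the residual. Constants and linear ramps lie in the
#' smoother's null space and are removed exactly; with \eqn{\lambda = 500}
#' at 4 Hz the filter attenuates components below roughly 0.035 Hz, leaving
#' the LF and HF bands essentially untouched.
#'
#' @param x Numeric vector, evenly sampled, length >= 3.
#' @param lambda Smoothing parameter (dimensionless, default 500).
#' @return Numeric vector of detrended values, same length as `x`.
#' @examples
#' z <- seq(0, 10, length.out = 100) + sin(2 * pi * 0.25 * seq(0, 24.75, by = 0.25))
#' max(abs(detrend_smoothness_priors(seq(0, 10, length.out = 100))))
#' @export
detrend_smoothness_priors <- function(x, lambda = 500) {
  n <- length(x)
  if (n < 3) stop("detrending needs at least 3 samples")
  stopifnot(lambda >= 0)
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  a <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2)
  trend <- Matrix::solve(a, x)
  as.numeric(x - trend)
}

# cubic-spline resampling of RR vs beat time onto a uniform grid
resample_tachogram <- function(series, rate = 4) {
  check_ibi(series)
  if (nrow(series) < 4) stop("too few beats to resample")
  t <- series$time
  grid <- seq(t[1], t[length(t)], by = 1 / rate)
  s <- spline(t, series$rr, xout = grid, method = "fmm")
  tibble::tibble(time = grid, rr = s$y)
}

# Welch PSD: averaged Hann-windowed periodograms, one-sided density scaled
# so that the integral over frequency approximates the signal variance.
welch_psd <- function(x, fs, n_seg, overlap = 0.5) {
  n <- length(x)
  if (n_seg > n) stop("series too short for one Welch segment")
  step <- max(1L, floor(n_seg * (1 - overlap)))
  starts <- seq(1L, n - n_seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_seg) / (n_seg + 1))) # Hann
  u <- sum(w^2)
  n_freq <- floor(n_seg / 2) + 1
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)] * w
    p <- Mod(fft(seg))^2 / (fs * u)
    p <- p[seq_len(n_freq)]
    # one-sided: double all bins except DC (and Nyquist for even lengths)
    dbl <- 2:(n_freq - if (n_seg %% 2 == 0) 1 else 0)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  tibble::tibble(
    freq = (seq_len(n_freq) - 1) * fs / n_seg,
    density = acc / length(starts)
  )
}

# trapezoidal band power over [low, high)
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  f <- psd$freq[sel]
  d <- psd$density[sel]
  if (length(f) < 2) return(0)
  sum(diff(f) * (d[-1] + d[-length(d)]) / 2)
}

#' Frequency-domain HRV indices
#'
#' Cubic-spline interpolation of the RR tachogram onto a uniform grid,
#' smoothness-priors detrending, Welch power spectral density (Hann
#' windows, overlapping segments), and trapezoidal band powers over the LF
#' (0.04–0.15 Hz) and HF (0.15–0.4 Hz) bands (closed at the lower, open at
#' the upper edge). Normalized units rescale each band to a percentage of
#' LF + HF, so `lf_nu + hf_nu = 100` by construction.
#'
#' @param series A cleaned ~5-min IBI tibble.
#' @param lambda Detrending parameter, see [detrend_smoothness_priors()].
#' @param resample_rate Interpolation rate, Hz (default 4; must exceed twice
#'   the upper HF edge).
#' @param segment_length Welch segment length, s (default 150; with 50%
#'   overlap this gives 3 segments in 5 min).
#' @param overlap Segment overlap fraction.
#' @param lf_band,hf_band Band edges, Hz.
#' @return An object of class `hrv_spectrum`: list with `psd` (tibble of
#'   `freq`, `density` in ms^2/Hz) and the band summaries. [glance()]
#'   returns the one-row summary (`lf_power`, `hf_power` in ms^2, `lf_nu`,
#'   `hf_nu`); [autoplot()] draws the spectrum with shaded bands.
#' @examples
#' x <- simulate_ibi(mean_rr = 800, amp_hf = 20, f_hf = 0.25, duration = 300)
#' glance(hrv_spectrum(x))
#' @export
hrv_spectrum <- function(series, lambda = 500, resample_rate = 4,
                         segment_length = 150, overlap = 0.5,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  check_ibi(series)
  stopifnot(lf_band[1] < lf_band[2], hf_band[1] < hf_band[2],
            lf_band[2] <= hf_band[1])
  if (resample_rate <= 2 * hf_band[2]) {
    stop("resample_rate must exceed twice the upper HF edge")
  }
  tach <- resample_tachogram(series, resample_rate)
  detr <- detrend_smoothness_priors(tach$rr, lambda)
  psd <- welch_psd(detr, fs = resample_rate,
                   n_seg = round(segment_length * resample_rate),
                   overlap = overlap)
  lf <- band_power(psd, lf_band)
  hf <- band_power(psd, hf_band)
  if (lf + hf <= 1e-8) stop("zero power in LF + HF; normalized units undefined")
  structure(
    list(
      psd = psd,
      lf_power = lf, hf_power = hf,
      lf_nu = 100 * lf / (lf + hf), hf_nu = 100 * hf / (lf + hf),
      lf_band = lf_band, hf_band = hf_band
    ),
    class = "hrv_spectrum"
  )
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("HRV spectrum: LF %.1f ms^2 (%.1f nu), HF %.1f ms^2 (%.1f nu)\n",
              x$lf_power, x$lf_nu, x$hf_power, x$hf_nu))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.hrv_spectrum <- function(x, ...) {
  tibble::tibble(lf_power = x$lf_power, hf_power = x$hf_power,
                 lf_nu = x$lf_nu, hf_nu = x$hf_nu)
}

#' @exportS3Method generics::tidy
tidy.hrv_spectrum <- function(x, ...) x$psd

#' @exportS3Method ggplot2::autoplot
autoplot.hrv_spectrum <- function(object, ...) {
  bands <- tibble::tibble(
    band = c("LF", "HF"),
    lo = c(object$lf_band[1], object$hf_band[1]),
    hi = c(object$lf_band[2], object$hf_band[2])
  )
  ggplot2::ggplot(object$psd, ggplot2::aes(.data$freq, .data$density)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf,
                   fill = .data$band)
    ) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 0.5)) +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (ms^2 / Hz)),
                  fill = NULL, title = "RR tachogram spectrum")
}

#' All HRV indices for one recording
#'
#' Convenience wrapper combining [hrv_time_domain()], [hrv_spectrum()] and
#' [hrv_poincare()] into one row, the per-recording record consumed by the
#' study-level analysis.
#'
#' @param series A cleaned analysis-window IBI tibble.
#' @param ... Passed to [hrv_spectrum()].
#' @return A one-row tibble with the time-domain, spectral and Poincare
#'   indices.
#' @examples
#' x <- simulate_ibi(mean_rr = 850, amp_lf = 30, amp_hf = 15, noise_sd = 5,
#'                   duration = 300, seed = 2)
#' hrv_profile(x)
#' @export
hrv_profile <- function(series, ...) {
  dplyr::bind_cols(
    hrv_time_domain(series),
    glance(hrv_spectrum(series, ...)),
    hrv_poincare(series)
  )
}
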