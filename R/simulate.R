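#' Simulate a short-term RR tachogram
#'
#' Generates a chronological inter-beat-interval series as a sum of a mean
#' level, one low-frequency (LF) and one high-frequency (HF) sinusoid and
#' white noise:
#' \deqn{RR_i = \bar{RR} + A_{LF}\sin(2\pi f_{LF} t_i) +
#'   A_{HF}\sin(2\pi f_{HF} t_i + \phi) + \epsilon_i,\quad
#'   \epsilon_i \sim N(0, \sigma^2),}
#' with \eqn{t_i} the cumulative beat time. Sinusoid variance is known
#' (\eqn{A^2/2}), so spectral band-power estimators can be validated
#' analytically. This is a direct model of the RR values, not an
#' integral-pulse-frequency-modulation model: sufficient for exercising the
#' estimators, with no claim of physiological realism (no respiratory
#' coupling or baroreflex feedback).
#'
#' @param mean_rr Mean interval, ms.
#' @param amp_lf,amp_hf Sinusoid amplitudes, ms.
#' @param f_lf,f_hf Sinusoid frequencies, Hz. Defaults sit inside the
#'   conventional LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) bands.
#' @param noise_sd White-noise standard deviation, ms.
#' @param duration Minimum total duration, s; beats are appended until the
#'   cumulative time reaches it.
#' @param phase_hf HF phase offset \eqn{\phi}, radians.
#' @param seed Optional integer seed; a fixed seed reproduces the series.
#' @return An IBI tibble (see [ibi_series()]).
#' @examples
#' simulate_ibi(mean_rr = 800, duration = 10)
#' @export
simulate_ibi <- function(mean_rr = 800, amp_lf = 0, amp_hf = 0,
                         f_lf = 0.1, f_hf = 0.25, noise_sd = 0,
                         duration = 300, phase_hf = 0, seed = NULL) {
  stopifnot(mean_rr > 0, amp_lf >= 0, amp_hf >= 0, noise_sd >= 0, duration > 0)
  if (f_lf < 0 || f_hf < 0) stop("frequencies must be non-negative")
  if (amp_lf + amp_hf + 4 * noise_sd >= mean_rr) {
    stop("spec can yield non-positive intervals: require ",
         "amp_lf + amp_hf + 4*noise_sd < mean_rr")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  # generous preallocation: mean rate plus slack for slow beats
  n_max <- ceiling(1000 * duration / mean_rr) + 64
  rr <- numeric(n_max)
  t <- 0
  n <- 0
  eps <- 1e-9 * duration # guard against accumulated floating-point error
  while (t < duration - eps) {
    n <- n + 1
    if (n > length(rr)) rr <- c(rr, numeric(64))
    val <- mean_rr +
      amp_lf * sin(2 * pi * f_lf * t) +
      amp_hf * sin(2 * pi * f_hf * t + phase_hf) +
      (if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0)
    rr[n] <- val
    t <- t + val / 1000
  }
  rr <- rr[seq_len(n)]
  if (any(rr <= 0)) stop("simulated series contains non-positive intervals")
  ibi_series(rr, id = "simulated")
}

#' Inject known artifacts into an IBI series
#'
#' Provides ground truth for validating artifact detection. Three kinds:
#' `"spike"` adds `magnitude` ms to the chosen intervals (an isolated
#' mistimed beat), `"missed_beat"` replaces an interval and its successor by
#' their sum (a dropped detection), `"extra_beat"` splits an interval into
#' two halves (a spurious detection).
#'
#' @param series An IBI tibble.
#' @param kind One of `"spike"`, `"missed_beat"`, `"extra_beat"`.
#' @param positions Beat indices (input indexing) to corrupt; alternatively
#'   give `rate`.
#' @param rate Artifacts per minute; positions are then drawn uniformly
#'   (seeded, reproducible).
#' @param magnitude Spike offset in ms (may be negative); ignored otherwise.
#' @param seed Optional integer seed used for rate-based position draws.
#' @return The corrupted IBI tibble with a logical `injected` column marking
#'   affected rows (output indexing); `which(out$injected)` is the ground
#'   truth index set.
#' @examples
#' x <- simulate_ibi(mean_rr = 800, duration = 60)
#' inject_artifacts(x, "spike", positions = 10, magnitude = 300)
#' @export
inject_artifacts <- function(series, kind = c("spike", "missed_beat", "extra_beat"),
                             positions = NULL, rate = NULL, magnitude = NULL,
                             seed = NULL) {
  check_ibi(series)
  kind <- match.arg(kind)
  n <- nrow(series)
  if (is.null(positions)) {
    if (is.null(rate)) stop("give either `positions` or `rate`")
    if (!is.null(seed)) set.seed(as.integer(seed))
    n_art <- max(0L, round(rate * ibi_duration(series) / 60))
    positions <- sort(sample.int(max(1L, n - 1L), min(n_art, n - 1L)))
  }
  positions <- as.integer(positions)
  max_pos <- if (kind == "missed_beat") n - 1L else n
  if (length(positions) && (any(positions < 1L) || any(positions > max_pos))) {
    stop("artifact position out of range")
  }
  if (kind == "spike") {
    if (is.null(magnitude) || magnitude == 0) stop("spike requires a non-zero magnitude")
  }

  rr <- series$rr
  flag <- logical(n)
  # process from the end so earlier indices stay valid under length changes
  for (p in sort(unique(positions), decreasing = TRUE)) {
    if (kind == "spike") {
      rr[p] <- rr[p] + magnitude
      flag[p] <- TRUE
    } else if (kind == "missed_beat") {
      rr[p] <- rr[p] + rr[p + 1]
      rr <- rr[-(p + 1)]
      fl <- flag[-(p + 1)]
      fl[p] <- TRUE
      flag <- fl
    } else { # extra_beat
      rr <- append(rr[-p], rep(rr[p] / 2, 2), after = p - 1)
      fl <- append(flag[-p], rep(TRUE, 2), after = p - 1)
      flag <- fl
    }
  }
  if (any(rr <= 0)) stop("injection produced a non-positive interval")
  out <- ibi_series(rr, id = attr(series, "source_id"))
  out$injected <- flag
  out
}

#' Simulate correlated bivariate-normal samples
#'
#' Draws `n` pairs from a bivariate normal with the given means, standard
#' deviations and correlation, the ground-truth generator for validating
#' the Bayesian correlation model.
#'
#' @param n Number of pairs (>= 3).
#' @param rho True correlation, in (-1, 1).
#' @param mu1,mu2 Means.
#' @param sigma1,sigma2 Standard deviations (> 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x` and `y`.
#' @examples
#' d <- simulate_bivariate(100, rho = 0.8, seed = 1)
#' cor(d$x, d$y)
#' @export
simulate_bivariate <- function(n, rho = 0, mu1 = 0, mu2 = 0,
                               sigma1 = 1, sigma2 = 1, seed = NULL) {
  stopifnot(n >= 3, sigma1 > 0, sigma2 > 0)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(x = mu1 + sigma1 * z1, y = mu2 + sigma2 * z2)
}
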