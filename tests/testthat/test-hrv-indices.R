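test_that("time-domain indices match hand computation", {
  const <- hrv_time_domain(constant_series(100))
  expect_equal(const$mean_rr, 800)
  expect_equal(const$sdnn, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$pnn50, 0)
  expect_equal(const$mean_hr, 75)
  expect_equal(const$min_hr, 75)
  expect_equal(const$max_hr, 75)

  # d = (60, -50, 55): two of three exceed 50 ms strictly
  hand <- hrv_time_domain(ibi_series(c(800, 860, 810, 865)))
  expect_equal(hand$pnn50, 200 / 3)
  expect_equal(hand$rmssd, sqrt((60^2 + 50^2 + 55^2) / 3))

  alt <- hrv_time_domain(ibi_series(rep(c(780, 860), 50)))
  expect_equal(alt$rmssd, 80)
  expect_error(hrv_time_domain(ibi_series(800)), "at least 2")
})

test_that("Poincare descriptors: exact cases and defining identities", {
  const <- hrv_poincare(constant_series(50))
  expect_equal(const$sd1, 0)
  expect_equal(const$sd2, 0)

  alt <- hrv_poincare(ibi_series(rep(c(780, 860), 50)))
  expect_equal(alt$sd1, 80 / sqrt(2), tolerance = 0.01)

  for (seed in 1:5) {
    x <- noisy_series(seed = seed, duration = 300)
    td <- hrv_time_domain(x)
    pc <- hrv_poincare(x)
    # sd1 ~ rmssd/sqrt(2) when the mean successive difference is ~0
    expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 0.02)
    # 2*sdnn^2 = sd1^2 + sd2^2
    expect_equal(pc$sd1^2 + pc$sd2^2, 2 * td$sdnn^2, tolerance = 0.01)
  }
})

test_that("smoothness-priors detrend annihilates constants and ramps", {
  expect_equal(detrend_smoothness_priors(rep(5, 200)), rep(0, 200),
               tolerance = 1e-10)
  ramp <- seq(0, 100, length.out = 400)
  out <- detrend_smoothness_priors(ramp)
  expect_lt(max(abs(out)), 1e-6 * diff(range(ramp)))
  expect_error(detrend_smoothness_priors(c(1, 2)), "at least 3")
})

test_that("detrend passes a mid-band sinusoid riding on a ramp", {
  t <- seq(0, 300, by = 0.25) # 4 Hz
  sine <- 10 * sin(2 * pi * 0.25 * t)
  out <- detrend_smoothness_priors(5 + 0.1 * t + sine, lambda = 500)
  err <- out - sine
  # the smoother leaks oscillation into the trend only near the boundaries;
  # away from them the sinusoid passes essentially untouched
  interior <- 100:(length(err) - 100)
  expect_lt(sqrt(mean(err[interior]^2)), 0.02 * 10)
  expect_lt(sqrt(mean(err^2)), 0.05 * 10)
})

test_that("band power recovers pure-tone variance A^2/2", {
  hf <- simulate_ibi(800, amp_hf = 20, f_hf = 0.25, duration = 300)
  g <- glance(hrv_spectrum(hf))
  expect_equal(g$hf_power, 200, tolerance = 0.1)
  expect_lt(g$lf_nu, 5)

  lf <- simulate_ibi(800, amp_lf = 30, f_lf = 0.1, duration = 300)
  g2 <- glance(hrv_spectrum(lf))
  expect_equal(g2$lf_power, 450, tolerance = 0.1)
  expect_gt(g2$lf_nu, 95)
})

test_that("normalized units always sum to 100", {
  for (seed in 1:5) {
    x <- simulate_ibi(800, amp_lf = 25, amp_hf = 12, noise_sd = 10,
                      duration = 300, seed = seed)
    g <- glance(hrv_spectrum(x))
    expect_equal(g$lf_nu + g$hf_nu, 100, tolerance = 1e-9)
  }
})

test_that("total spectral power matches time-domain variance (Parseval)", {
  x <- simulate_ibi(800, amp_lf = 30, amp_hf = 20, duration = 300, seed = 2)
  spec <- hrv_spectrum(x)
  psd <- tidy(spec)
  total <- sum(diff(psd$freq) * (psd$density[-1] + psd$density[-nrow(psd)]) / 2)
  # variance of the detrended resampled tachogram it was computed from
  tach <- hrvbayes:::resample_tachogram(x, 4)
  v <- mean(detrend_smoothness_priors(tach$rr)^2)
  expect_equal(total, v, tolerance = 0.1)
})

test_that("windowed indices ignore padding outside the analysis window", {
  core <- simulate_ibi(800, amp_hf = 15, noise_sd = 10, duration = 320, seed = 9)
  padded <- ibi_series(c(rep(700, 100), core$rr))
  a <- hrv_profile(ibi_analysis_window(core, 300))
  b <- hrv_profile(ibi_analysis_window(padded, 300))
  expect_equal(a, b)
})

test_that("spectrum guards its preconditions", {
  x <- simulate_ibi(800, amp_hf = 10, duration = 300)
  expect_error(hrv_spectrum(x, resample_rate = 0.5), "twice")
  expect_error(hrv_spectrum(ibi_analysis_window(x, 60)), "segment")
  expect_error(hrv_spectrum(constant_series(400)), "zero power")
})
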