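test_that("IBI text round-trip preserves intervals; parse errors name the line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("800", "810", "790"), f)
  x <- read_ibi(f)
  expect_equal(x$rr, c(800, 810, 790))

  g <- withr::local_tempfile(fileext = ".txt")
  write_ibi(x, g)
  expect_equal(read_ibi(g)$rr, x$rr)

  writeLines(character(0), f)
  expect_error(read_ibi(f), "empty")
  writeLines(c("800", "abc", "790"), f)
  expect_error(read_ibi(f), "line 2")
  writeLines(c("800", "", "790"), f) # blank lines are fine
  expect_equal(nrow(read_ibi(f)), 2)
  writeLines(c("800", "-5"), f)
  expect_error(read_ibi(f), "line 2")
})

test_that("window selection takes the maximal suffix within the duration", {
  x <- simulate_ibi(800, duration = 600)
  expect_equal(nrow(ibi_detection_window(x, 360)), 450)
  exact <- simulate_ibi(800, duration = 360)
  expect_equal(nrow(ibi_detection_window(exact, 360)), nrow(exact))
  short <- simulate_ibi(800, duration = 300)
  expect_error(ibi_detection_window(short, 360), "shorter")
  expect_error(ibi_analysis_window(x, 0), "positive")
  # cleaned 360 s constant series -> 375 beats in the 300 s analysis window
  expect_equal(nrow(ibi_analysis_window(exact, 300)), 375)
})

test_that("an injected spike is flagged exactly, a clean series nearly never", {
  x <- noisy_series(seed = 21)
  spiked <- inject_artifacts(x, "spike", positions = 100, magnitude = 300)
  rep <- detect_artifacts(spiked)
  expect_true(100 %in% rep$flagged)
  expect_lte(length(rep$flagged), 2)
  expect_equal(rep$artifact_pct,
               artifact_percentage(length(rep$flagged), nrow(spiked)))
})

test_that("false-positive rate on clean Gaussian series is below 1%", {
  flagged <- 0
  total <- 0
  for (seed in 1:100) {
    x <- simulate_ibi(800, noise_sd = 20, duration = 321, seed = seed) # ~400 beats
    rep <- detect_artifacts(x)
    flagged <- flagged + length(rep$flagged)
    total <- total + rep$total_points
  }
  expect_lt(flagged / total, 0.01)
})

test_that("recall is 100% for spikes at least twice the threshold", {
  for (seed in 1:50) {
    x <- noisy_series(seed = seed)
    t0 <- detect_artifacts(x)$threshold
    pos <- c(50, 150, 300)
    spiked <- inject_artifacts(x, "spike", positions = pos,
                               magnitude = ceiling(2 * t0) + 1)
    rep <- detect_artifacts(spiked)
    expect_true(all(pos %in% rep$flagged))
  }
})

test_that("removal deletes flagged beats; re-detection finds almost nothing new", {
  x <- noisy_series(seed = 33)
  spiked <- inject_artifacts(x, "spike", positions = c(60, 200), magnitude = 300)
  rep <- detect_artifacts(spiked)
  clean <- remove_artifacts(spiked, rep)
  expect_equal(nrow(clean), nrow(spiked) - length(rep$flagged))
  rep2 <- detect_artifacts(clean)
  expect_lte(length(rep2$flagged), 2)

  # empty flag set returns the identical series
  quiet <- detect_artifacts(x)
  if (length(quiet$flagged) == 0) expect_identical(remove_artifacts(x, quiet), x)
  expect_error(remove_artifacts(constant_series(10), rep), "length mismatch")
})

test_that("degenerate inputs: too few beats, zero variance", {
  expect_error(detect_artifacts(constant_series(5)), "at least 8")
  expect_warning(rep0 <- detect_artifacts(constant_series(50)), "zero variance")
  expect_equal(length(rep0$flagged), 0)
  expect_false(rep0$disqualified)
})

test_that("disqualification is monotone in the injected artifact rate", {
  pcts <- vapply(c(0.5, 2, 6, 12), function(rate) {
    x <- noisy_series(seed = 77, duration = 400)
    spiked <- inject_artifacts(x, "spike", rate = rate, magnitude = 400, seed = 5)
    detect_artifacts(ibi_detection_window(spiked, 360))$artifact_pct
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
  x <- noisy_series(seed = 77, duration = 400)
  heavy <- inject_artifacts(x, "spike", rate = 12, magnitude = 400, seed = 5)
  expect_true(detect_artifacts(ibi_detection_window(heavy, 360))$disqualified)
})

test_that("clean_ibi chains windowing, detection and removal", {
  x <- simulate_ibi(820, noise_sd = 15, duration = 600, seed = 55)
  spiked <- inject_artifacts(x, "spike", positions = c(400, 500), magnitude = 350)
  out <- clean_ibi(spiked)
  expect_s3_class(out$report, "artifact_report")
  expect_lte(ibi_duration(out$series), 300)
  expect_gt(ibi_duration(out$series), 295)
  expect_error(clean_ibi(x, detection_window = 200, analysis_window = 300),
               "cannot exceed")
})

test_that("report accessors give per-beat and summary views", {
  x <- noisy_series(seed = 3)
  spiked <- inject_artifacts(x, "spike", positions = 42, magnitude = 350)
  rep <- detect_artifacts(spiked)
  td <- tidy(rep)
  expect_equal(nrow(td), nrow(spiked))
  expect_true(td$artifact[42])
  g <- glance(rep)
  expect_equal(g$n_flagged, length(rep$flagged))
  expect_equal(g$total_points, nrow(spiked))
})
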