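test_that("degenerate inputs are rejected", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  expect_error(bayes_cor(d, x, y), "collinear")
  expect_error(bayes_cor(tibble::tibble(x = rep(1, 10), y = rnorm(10)), x, y),
               "zero-variance")
  expect_error(bayes_cor(tibble::tibble(x = c(1, NA, 3), y = 1:3), x, y),
               "at least 3|non-finite")
  expect_error(bayes_describe(tibble::tibble(v = rep(2, 10)), v), "zero-variance")
})

test_that("posterior concentrates on the generating correlation at n = 1000", {
  d <- simulate_bivariate(1000, rho = 0.8, seed = 4)
  fit <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 4, n_save = 3000))
  g <- glance(fit)
  expect_lt(abs(g$rho_median - 0.8), 0.05)
  expect_lt(g$hdi_upper - g$hdi_lower, 0.1)
  expect_equal(g$decision, "credible")

  d0 <- simulate_bivariate(1000, rho = 0, seed = 5)
  g0 <- glance(bayes_cor(d0, x, y, mcmc = quick_mcmc(seed = 5, n_save = 3000)))
  expect_lte(g0$hdi_lower, 0)
  expect_gte(g0$hdi_upper, 0)
  expect_equal(g0$decision, "unclear")
})

test_that("posterior median rho tracks the sample Pearson r", {
  for (seed in 1:3) {
    d <- simulate_bivariate(200, rho = 0.3, seed = seed)
    fit <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = seed, n_save = 4000))
    s <- tidy(fit)
    rho_row <- s[s$term == "rho", ]
    expect_lt(abs(rho_row$estimate - cor(d$x, d$y)), 3 * rho_row$mcse + 0.005)
  }
})

test_that("fits are reproducible for a fixed seed and stable across seeds", {
  d <- simulate_bivariate(500, rho = 0.5, seed = 6)
  f1 <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 10, n_save = 3000))
  f2 <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 10, n_save = 3000))
  expect_identical(f1$draws, f2$draws)

  f3 <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 11, n_save = 3000))
  m1 <- tidy(f1)[tidy(f1)$term == "rho", ]
  m3 <- tidy(f3)[tidy(f3)$term == "rho", ]
  # each median carries its own Monte Carlo error; compare at 2 SE combined
  expect_lt(abs(m3$estimate - m1$estimate),
            2 * sqrt(m1$mcse^2 + m3$mcse^2))
})

test_that("saved-draw quotas split the total across chains, remainder first", {
  fit <- bayes_cor(simulate_bivariate(50, 0.2, seed = 1), x, y,
                   mcmc = mcmc_config(n_save = 2000, seed = 1))
  counts <- table(fit$draws$chain)
  expect_equal(as.integer(counts), c(668, 666, 666))
  expect_equal(sum(counts), 2000)
  fit2 <- bayes_cor(simulate_bivariate(50, 0.2, seed = 1), x, y,
                    mcmc = mcmc_config(n_save = 300, per_chain = TRUE, seed = 1))
  expect_equal(as.integer(table(fit2$draws$chain)), rep(300, 3))
})

test_that("draws respect parameter supports", {
  fit <- bayes_cor(simulate_bivariate(40, -0.5, seed = 8), x, y,
                   mcmc = quick_mcmc(seed = 8))
  expect_true(all(fit$draws$sigma1 > 0))
  expect_true(all(fit$draws$sigma2 > 0))
  expect_true(all(abs(fit$draws$rho) < 1))
})

test_that("univariate posterior recovers mean and SD at large n", {
  d <- tibble::tibble(v = rnorm(1e4, 873, 59))
  fit <- bayes_describe(d, v, mcmc = quick_mcmc(seed = 12, n_save = 3000))
  g <- glance(fit)
  expect_lt(abs(g$mu_median - 873), 2)
  expect_lt(abs(g$sigma_median - 59), 2)
  f2 <- bayes_describe(d, v, mcmc = quick_mcmc(seed = 12, n_save = 3000))
  expect_identical(fit$draws, f2$draws)
})

test_that("shortest interval matches normal quantiles and beats equal tails", {
  expect_error(hdi(rnorm(50)), "at least 100")
  h0 <- hdi(rep(3.5, 200))
  expect_equal(c(h0$lower, h0$upper), c(3.5, 3.5))

  set.seed(101)
  z <- rnorm(1e5)
  h <- hdi(z)
  expect_lt(abs(h$lower + 1.96), 0.05)
  expect_lt(abs(h$upper - 1.96), 0.05)
  # mass property: at least 95% of draws inside (up to one draw)
  expect_gte(mean(z >= h$lower & z <= h$upper), 0.95 - 1 / length(z))

  sk <- rlnorm(2e4, 0, 0.8)
  hs <- hdi(sk)
  eq <- quantile(sk, c(0.025, 0.975))
  expect_lt(hs$upper - hs$lower, eq[2] - eq[1])
})

test_that("PSRF separates mixed from unmixed chains", {
  set.seed(7)
  expect_lt(psrf(list(rnorm(2000), rnorm(2000), rnorm(2000))), 1.01)
  expect_gt(psrf(list(rnorm(2000), rnorm(2000, 10))), 1.1)
  expect_error(psrf(list(rnorm(100))), "2 chains")
})

test_that("ESS matches the AR(1) closed form and the i.i.d. limit", {
  set.seed(9)
  n <- 50000
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), n))
  expect_equal(ess(ar), n * (1 - phi) / (1 + phi), tolerance = 0.2)
  iid <- rnorm(n)
  expect_gt(ess(iid), 0.8 * n)
  expect_lte(ess(iid), n)
  expect_equal(mcse(iid), sd(iid) / sqrt(ess(iid)))
})

test_that("per-parameter summaries carry healthy diagnostics", {
  fit <- bayes_cor(simulate_bivariate(100, 0.6, seed = 13), x, y,
                   mcmc = quick_mcmc(seed = 13, n_save = 3000))
  s <- tidy(fit)
  expect_equal(s$term, c("mu1", "mu2", "sigma1", "sigma2", "rho"))
  expect_true(all(s$psrf < 1.1))
  expect_true(all(s$ess > 100))
  expect_true(all(s$mcse > 0))
  expect_true(all(s$hdi_lower <= s$estimate & s$estimate <= s$hdi_upper))
})

test_that("posterior predictive ellipse containment calibrates", {
  d <- simulate_bivariate(1000, rho = 0.6, seed = 14)
  fit <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 14, n_save = 3000))
  pc <- ppc_ellipse(fit)
  expect_equal(pc$containment, 0.95, tolerance = 0.03)
  expect_true(pc$pass)

  # all data at the posterior centre -> full containment
  centred <- fit
  centred$data <- tibble::tibble(x = rep(pc$mu1, 20), y = rep(pc$mu2, 20))
  expect_equal(ppc_ellipse(centred)$containment, 1)

  # grossly shifted data -> no containment
  shifted <- fit
  shifted$data <- fit$data + 10
  expect_equal(ppc_ellipse(shifted)$containment, 0)
})

test_that("effect-size bins and HDI decision rule", {
  expect_equal(classify_effect_size(0.05), "negligible")
  expect_equal(classify_effect_size(0.15), "small")
  expect_equal(classify_effect_size(0.35), "medium")
  expect_equal(classify_effect_size(-0.68), "large")
  expect_equal(classify_effect_size(c(0.29, 0.3)), c("small", "medium"))
  expect_error(classify_effect_size(1.2), "rho")

  expect_equal(hdi_decision(0.001, 0.918), "credible")
  expect_equal(hdi_decision(-0.935, -0.064), "credible")
  expect_equal(hdi_decision(-0.378, 0.793), "unclear")
  expect_equal(hdi_decision(0, 0.5), "unclear") # touching zero is not exclusion
  expect_error(hdi_decision(0.5, 0.1), "exceeds")
})

test_that("plot constructors return ggplot objects", {
  d <- simulate_bivariate(100, rho = 0.5, seed = 15)
  fit <- bayes_cor(d, x, y, mcmc = quick_mcmc(seed = 15))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_ppc(fit), "ggplot")
  x <- simulate_ibi(800, amp_hf = 15, noise_sd = 10, duration = 300, seed = 1)
  expect_s3_class(autoplot(hrv_spectrum(x)), "ggplot")
  expect_s3_class(plot_poincare(x), "ggplot")
})
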