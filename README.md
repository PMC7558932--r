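# hrvbayes

Short-term heart-rate-variability (HRV) analysis with Bayesian correlation
estimation, for researchers in sport science, psychophysiology and
cardiovascular epidemiology who work with small cohorts.

Beat-to-beat fluctuation of the inter-beat interval (IBI) reflects the
balance of parasympathetic and sympathetic drive to the heart. The package
covers the full workflow from a raw IBI recording to a study-level
correlation report:

* **Cleaning** — plain-text IBI files in, artifact screening on the last
  6 minutes with a quartile-trimmed threshold rule on successive interval
  differences ($T = k\hat\sigma$, $\hat\sigma$ = SD of the central 50% of
  differences / 0.3776, $k = 3.29$), deletion of flagged beats, a ≥5%
  disqualification rule, and the last clean 5 minutes kept for analysis.
* **Indices** — time domain (MeanRR, SDNN, RMSSD, pNN50, heart-rate
  summaries); frequency domain via cubic-spline resampling at 4 Hz,
  smoothness-priors detrending ($\lambda = 500$) and Welch band power in
  LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz), absolute (ms²) and normalized
  units; Poincaré SD1/SD2.
* **Bayesian correlation** — bivariate-normal likelihood with broad
  data-scaled priors, sampled by a native compiled component-wise
  Metropolis sampler (3 chains, 500 adapt, 500 burn-in, thin 10, 20,000
  saved draws by default). Associations are posterior medians of $\rho$
  with 95% highest-density intervals (HDI); a pair is *credible* only when
  the HDI excludes zero, with Cohen effect-size bins on $|\rho|$.
  Diagnostics: Gelman–Rubin PSRF, effective sample size, Monte Carlo
  standard error, and posterior predictive ellipse checks.
* **Synthetic data** — tachograms with known band power, artifact
  injections with ground truth, correlated bivariate samples and a full
  synthetic study generator, so every stage is testable end to end.

Everything is tibble-first and pipe-friendly, with broom-style `tidy()` /
`glance()` methods and ggplot2 `autoplot()` / `plot_*()` helpers.

## Worked example

Simulate a 10-minute resting recording with two injected spike artifacts,
clean it, and compute the indices:

```r
library(hrvbayes)

raw <- simulate_ibi(mean_rr = 870, amp_lf = 37, amp_hf = 19, noise_sd = 8,
                    duration = 600, seed = 42)
rec <- inject_artifacts(raw, "spike", positions = c(250, 480), magnitude = 350)
cleaned <- clean_ibi(rec)
glance(cleaned$report)
#> # A tibble: 1 × 5
#>   total_points n_flagged artifact_pct threshold disqualified
#>          <int>     <int>        <dbl>     <dbl> <lgl>
#> 1          413         1          0.2      82.6 FALSE

round(hrv_profile(cleaned$series), 1)
#>   mean_rr sdnn rmssd pnn50 mean_hr min_hr max_hr lf_power hf_power lf_nu hf_nu  sd1  sd2
#> 1   868.9   31    25   3.5    69.1   64.1   74.9    725.1    192.9    79    21 17.7 40.1
```

The detection window is the last 6 minutes (413 beats here), one spike
falls inside it and is flagged (0.2% — far below the 5% disqualification
cutoff; the other lies before the window). The indices are computed on the
last clean 5 minutes: mean interval 869 ms (heart rate 69 bpm), overall
variability SDNN 31 ms, vagal markers RMSSD 25 ms / pNN50 3.5%, LF power
725 ms² (79 normalized units), HF 193 ms² (21 nu), Poincaré SD1 17.7 /
SD2 40.1 ms — resting values typical of a middle-aged adult.

Then estimate an association at study level (8 participants):

```r
study <- simulate_study(seed = 42)
fit <- bayes_cor(study$participants, sdnn, rpp, mcmc = mcmc_config(seed = 42))
fit
#> Bayesian correlation sdnn ~ rpp: rho = -0.691, 95% HDI (-0.968, -0.128), credible (large)

tidy(fit)
#> # A tibble: 5 × 7
#>   term   estimate hdi_lower hdi_upper  psrf    ess    mcse
#>   <chr>     <dbl>     <dbl>     <dbl> <dbl>  <dbl>   <dbl>
#> 1 mu1      32.2      27.5      36.9   1.00   8889. 0.0253
#> 2 mu2    9570.     8453.    10720.    1.00   9599. 5.83
#> 3 sigma1    5.98      3.17     10.7   1.000 11619. 0.0207
#> 4 sigma2 1425.      760.     2553.    1.000 11095. 5.05
#> 5 rho      -0.691    -0.968    -0.128 1.00  15266. 0.00199
```

For this simulated cohort the SDNN–RPP posterior median is −0.69 with a
95% HDI of (−0.97, −0.13): the interval excludes zero, so the association
is labelled credible, with a large effect size. PSRF ≈ 1 and effective
sample sizes in the thousands indicate well-mixed chains; `plot_ppc(fit)`
overlays the model's predictive ellipses on the data. With n = 8 the
intervals are wide — exactly the behaviour the HDI decision rule is meant
to surface. Use `bayes_correlation_matrix()` /
`correlation_report()` for the full pairwise report and
`bayes_describe_table()` for Bayesian descriptive summaries with the
normality screen.

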