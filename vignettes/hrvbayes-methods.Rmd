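---
title: "Heart rate variability indices and Bayesian correlation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart rate variability indices and Bayesian correlation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvbayes)
```

hrvbayes implements a complete short-term heart-rate-variability (HRV)
analysis: cleaning of inter-beat-interval (IBI) recordings, time-domain,
frequency-domain and Poincaré indices, and Bayesian estimation of pairwise
correlations between HRV indices and cardiovascular or aerobic covariates,
with highest-density-interval (HDI) decision rules and convergence
diagnostics. This vignette explains the models, the parameters that matter,
and the design choices made where the methodology left them open.

## The pipeline at a glance

```{r pipeline, eval = FALSE}
raw <- read_ibi("recording.txt")
cleaned <- clean_ibi(raw) # last 6 min screened, last clean 5 min kept
profile <- hrv_profile(cleaned$series) # MeanRR, SDNN, ..., LF/HF, SD1/SD2
fit <- bayes_cor(study_table, sdnn, rpp, mcmc = mcmc_config(seed = 1))
glance(fit) # rho median, 95% HDI, credible/unclear, effect size
```

## Artifact identification

A mistimed or missed beat corrupts two successive interval differences in
opposite directions. The detector works on the differences
$d_i = RR_{i+1} - RR_i$:

1. quartiles $Q_1, Q_3$ of the differences are computed;
2. the artifact-free spread is estimated as the SD of the differences inside
   $[Q_1, Q_3]$ divided by 0.3776, the SD of a standard normal truncated to
   its central 50% — a trimmed, normal-consistent estimate that the
   artifacts themselves cannot inflate;
3. the threshold is $T = k\hat\sigma$ with $k = 3.29$ by default, the
   two-sided 99.9% normal quantile;
4. an interior beat is flagged when both adjacent differences exceed $T$
   with opposite signs (the isolated-outlier signature); the first and
   last beats use their single adjacent difference.

The exact numeric criterion of the distribution-based detectors implemented
in interactive editing tools is not published; the truncation correction
0.3776 and $k = 3.29$ are documented, normal-consistent choices and both
are arguments of `detect_artifacts()`, so they can be re-tuned if reference
outputs become available. Flagged beats are deleted, not interpolated,
mirroring the manual-deletion practice the pipeline emulates. Detection
runs on the last 6 minutes of the recording and the indices on the last
clean 5 minutes; which 5 of the 6 cleaned minutes to keep is not prescribed
anywhere, and taking the final suffix keeps the rule deterministic. A
recording with at least 5% flagged beats is marked disqualified. Reported
artifact percentages round half-up to one decimal.

Zero-variance input (a constant series) degenerates the threshold; the
detector warns and flags nothing rather than dividing by zero.

## Time-domain and Poincaré indices

SDNN is the sample SD of the intervals (divisor $N-1$); RMSSD averages the
$N-1$ squared successive differences over their count; pNN50 uses strict
$|d_i| > 50$ ms; heart-rate summaries are instantaneous ($60000/RR_i$),
not window-smoothed — the divisor and strictness conventions are stated
here because reporting software varies and silent differences of a few
percent are common. SD1 and SD2 derive from the identities
$SD1^2 = \mathrm{var}(d)/2$ and $SD2^2 = 2\,SDNN^2 - SD1^2$ (clipped at
zero), so the Poincaré identity $2\,SDNN^2 = SD1^2 + SD2^2$ holds by
construction and $SD1 \approx RMSSD/\sqrt2$ whenever the mean successive
difference is near zero.

## Spectral analysis

The irregularly sampled tachogram is cubic-spline interpolated onto a
uniform 4 Hz grid. A stated "500 Hz" sampling frequency in ECG-based
workflows refers to R-peak timing resolution, not a usable interpolation
rate; 4 Hz comfortably exceeds twice the upper HF edge (0.4 Hz) and is the
conventional choice.

Slow trend is removed by the smoothness-priors smoother: the trend is
$(I + \lambda^2 D_2^\top D_2)^{-1} z$ with $D_2$ the second-difference
operator, solved as a sparse banded system. $\lambda = 500$ — the standard
default of the method — gives a cutoff near 0.035 Hz at 4 Hz, below the LF
band. Constants and linear ramps are annihilated exactly. The smoother
leaks some oscillatory power into the trend within roughly 25 s of each
end of the record; over a 5-min window this contributes only a few percent
to band power and is shared by all implementations of the method.

The PSD is a Welch estimate: Hann-windowed 150 s segments with 50% overlap
(three segments in 5 minutes — a compromise between the single-window
convention and variance reduction), one-sided, density-scaled so the
integral over frequency approximates the variance of the detrended signal.
Band powers integrate the density by trapezoid over LF = [0.04, 0.15) Hz
and HF = [0.15, 0.4) Hz, closed at the lower and open at the upper edge so
the shared 0.15 Hz edge is counted once. Normalized units are
$100\,LF/(LF+HF)$ and $100\,HF/(LF+HF)$, so they sum to 100 exactly; VLF
and ULF are not reported for 5-min records. On a pure tone of amplitude
$A$ the band power recovers $A^2/2$ within a few percent (leakage at the
band edge accounts for the rest), which is the oracle the test suite uses.

## The Bayesian correlation model

For paired samples the likelihood is bivariate normal with parameters
$(\mu_1, \mu_2, \sigma_1, \sigma_2, \rho)$; the prerequisite is that both
variables are roughly normal and not too kurtotic, which is what the
normality screen (below) checks. Priors are broad and data-scaled, in the
style of Kruschke's estimation framework:

* $\mu_j \sim N(\bar x_j, (100\,s_j)^2)$
* $\sigma_j \sim \mathrm{Uniform}(s_j/1000,\ 1000\,s_j)$
* $\rho \sim \mathrm{Uniform}(-1, 1)$

The exact constants of the original adapted scripts are not published;
only the family is inferable, and with $n \ge 8$ these priors are
effectively flat relative to the likelihood. A Student-t robust variant is
a natural extension but is deliberately out of scope; the normality screen
is the gatekeeper instead.

The sampler is a component-wise random-walk Metropolis in the transformed
coordinates $(\mu_1, \mu_2, \log\sigma_1, \log\sigma_2,
\mathrm{atanh}\,\rho)$, so no proposal can land outside the support and no
boundary rejections bias the walk; the Jacobians are folded into the
target. The likelihood is evaluated from sufficient statistics, making one
evaluation O(1) in the sample size; the core loop is compiled (Rcpp) and a
full default fit takes well under a second. During the adaptation phase
proposal scales are adjusted every 50 steps toward an acceptance rate in
the 0.2–0.5 window and then frozen, so post-burn-in draws target the exact
posterior. All randomness flows through R's RNG: a fixed seed reproduces
every chain bit for bit.

Defaults follow common practice for this model class: 3 chains, 500
adaptation steps, 500 burn-in steps, thinning of 10, and 20,000 saved
draws interpreted as the total across chains (6,668/6,666/6,666; a
per-chain interpretation is available via `per_chain = TRUE`). Thinning is
applied while sampling until each chain reaches its saved-draw quota.

### HDI, decision rule and effect size

The 95% HDI is the shortest contiguous interval over the sorted draws
containing $\lceil 0.95\,n \rceil$ of them (ties to the lowest window).
Because credibility is equal everywhere inside the interval, an interval
that overlaps zero is not evidence of association: `hdi_decision()` labels
a pair `"credible"` only when both bounds share a sign. Effect sizes use
Cohen's bins on $|\rho|$: below 0.1 negligible, 0.1–0.29 small, 0.3–0.49
medium, above 0.5 large.

### Convergence diagnostics and model checking

`tidy()` on a fit reports, per parameter, the Gelman–Rubin potential scale
reduction factor across chains, the effective sample size from the
initial-positive-sequence autocorrelation estimator (summed over chains,
capped at the draw count), and the Monte Carlo standard error
$\mathrm{SD}/\sqrt{ESS}$. The posterior predictive check draws the
bivariate-normal ellipse of the posterior-median parameters at a given
credibility level and reports the fraction of observed points inside;
containment near the level indicates the model accommodates the data, and
the documented pass heuristic (containment $\ge 1 - 2(1 - level)$)
tolerates small-sample fluctuation.

## Study assembly

`screen_variables()` applies the Shapiro–Wilk test (p ≤ 0.05 cutoff),
bias-corrected (type-2) skewness and excess kurtosis — the estimator
family of mainstream statistics software, chosen because reported
kurtosis values in this literature are consistent with excess kurtosis —
and log-transforms a variable if and only if the raw screen fails,
re-screening afterwards. For samples beyond the Shapiro–Wilk limit of
5000 the test is applied to 5000 evenly spaced order statistics, which is
deterministic and preserves the distribution shape.

`bayes_correlation_matrix()` fits one correlation per variable pair and
reports the posterior median, HDI bounds, decision and effect label, with
`correlation_report()` reshaping to the conventional
rho / upper-HDI / lower-HDI row-triplet layout. No multiplicity adjustment
is applied across pairs: each interval is a marginal posterior statement,
and this is stated in the function documentation rather than silently
corrected, because the comparison target for this pipeline reports
unadjusted intervals. Note that normalized LF and HF units are estimated
independently per column in descriptive tables, so their posterior medians
need not sum to exactly 100 even though the underlying per-recording
values do.

The derived covariates are $RPP = HR \times SBP$,
$MAP = (SBP - DBP)/3 + DBP$ and allometric $\dot VO_2 = \dot
VO_2^{abs}/m^{0.67}$.

## What the synthetic data emulate — and what they do not

`simulate_ibi()` models RR values directly as mean + LF sinusoid + HF
sinusoid + white noise, with beat times accumulated from the intervals.
Sinusoid variance is $A^2/2$, so spectral estimators can be validated
against closed-form power; the validity constraint
$A_{LF} + A_{HF} + 4\sigma < \overline{RR}$ guarantees positive intervals.
The HF phase defaults to 0 and is configurable. This is not an
integral-pulse-frequency-modulation model and makes no claim of
physiological realism: there is no respiratory coupling, baroreflex
feedback or circadian drift. Passing tests therefore demonstrate that the
estimators recover known signal structure, not that they reproduce any
particular physiological population.

`inject_artifacts()` provides ground truth for the detector with spike,
missed-beat and extra-beat corruptions; `simulate_bivariate()` draws
correlated pairs for validating the correlation model.

`simulate_study()` assembles the full synthetic study. Its defaults are
fixed once to a realistic resting middle-aged female cohort: 12 enrolled,
2 excluded for BP medication and 2 for incomplete testing (8 analyzed);
between-participant MeanRR 873 ± 59 ms; LF and HF band powers near 696
and 179 ms²; SBP near 135 mmHg with pulse pressure near 61 mmHg (implying
resting RPP near 9300 mmHg·bpm and MAP near 94 mmHg); allometric VO2peak
near 123; breaths-per-minute lognormal so that the normality screen's
log-transform rule is exercised; spike artifacts injected at 0.3/min.
Resting heart rate is taken from the cleaned tachogram itself, so
$RPP = HR \times SBP$ and $DBP < MAP < SBP$ hold for every generated
record by construction. One master seed fans out to all stages through
`seed_stream()` (seed the base RNG once, draw 32-bit child seeds), making
the whole study bit-reproducible.

## Numerical choices and degenerate inputs

* Window selection takes the maximal suffix of beats whose summed duration
  fits the window; recordings shorter than the window are an error, as is
  an analysis window longer than the detection window.
* Perfectly collinear pairs and zero-variance columns are rejected before
  sampling (degenerate likelihood).
* The HDI requires at least 100 draws; PSRF at least two chains; chains of
  unequal saved length (the remainder rule) are aligned to the shortest
  for PSRF.
* `ess()` caps at the number of draws, so `mcse` is never smaller than the
  i.i.d. standard error.
* Band power below 1e-8 ms² in LF + HF (a constant tachogram) is treated
  as zero power and normalized units are refused rather than returned as
  0/0.

## Problem sizes used in the validation suite

The test suite validates the calibration of the HDI with 300 simulated
bivariate-normal datasets ($n = 50$, $\rho = 0.5$) fitted with a reduced
configuration (2,000 saved draws), chosen so the whole suite and the
reproduction script each complete in minutes on a single core while the
binomial tolerance (±3.5 percentage points at 95% coverage, 300 runs)
remains meaningful. Spectral oracles use 5-minute pure-tone tachograms;
artifact recall and false-positive rates use 25–100 seeded 6-minute
recordings.

## Known limitations

* The artifact detector targets isolated ectopics and spikes — the
  corruption the injection module produces; runs of consecutive artifacts
  would require a different flagging pattern.
* The spectral estimate inherits Welch bias-variance trade-offs; with
  three 150 s segments, narrowband power estimates at the band edges carry
  leakage of a few percent.
* The correlation model is bivariate normal only; heavy-tailed data should
  be transformed (the screen automates the log case) or handled outside
  this package.
* Normalized spectral units are compositional; their correlations with
  other indices inherit the usual closure artefacts and should be read
  accordingly.
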