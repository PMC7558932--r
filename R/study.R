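#' Simulate a complete study table
#'
#' End-to-end synthetic study generator: an enrolled cohort with exclusion
#' flags ([simulate_cohort()]), then for each analyzable participant a
#' 10-minute RR tachogram with LF/HF oscillations, white noise and a few
#' injected spike artifacts, cleaned through the detection/analysis windows
#' ([clean_ibi()]) and summarised into HRV indices ([hrv_profile()]),
#' joined with blood-pressure and aerobic-capacity covariates. Resting
#' heart rate is the mean instantaneous heart rate of the clean window, so
#' the derived quantities satisfy `rpp = rest_hr * sbp` and
#' `dbp < map < sbp` for every record.
#'
#' Tachogram defaults (MeanRR 873 +/- 59 ms across participants, LF power
#' near 696 ms^2 and HF power near 179 ms^2 via amplitudes \eqn{\sqrt{2P}},
#' lognormal breaths-per-minute) emulate a resting middle-aged female
#' cohort; one master seed fans out to all stages via [seed_stream()].
#'
#' @param n_enrolled,n_medicated,n_incomplete Cohort composition, see
#'   [simulate_cohort()].
#' @param mean_rr_mean,mean_rr_sd Between-participant MeanRR distribution, ms.
#' @param lf_power,hf_power Target band powers, ms^2 (sinusoid amplitudes
#'   are \eqn{\sqrt{2P}}, jittered 20% between participants).
#' @param noise_sd Within-tachogram white-noise SD, ms.
#' @param artifact_rate Injected spike artifacts per minute.
#' @param artifact_magnitude Spike offset, ms.
#' @param seed Master seed (integer); fixed seed reproduces the study.
#' @return A list with `participants` (one row per analyzed participant:
#'   HRV indices plus `sbp`, `dbp`, `rest_hr`, `rpp`, `map`,
#'   `vo2peak_allometric`, `rer`, `bpm_breaths`, `hr_max`,
#'   `time_to_exhaustion`), `cohort` (the enrolment table) and
#'   `artifact_reports` (per-recording [glance()] rows).
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 1)
#' study$participants
#' }
#' @export
simulate_study <- function(n_enrolled = 12, n_medicated = 2, n_incomplete = 2,
                           mean_rr_mean = 873, mean_rr_sd = 59,
                           lf_power = 696, hf_power = 179, noise_sd = 8,
                           artifact_rate = 0.3, artifact_magnitude = 350,
                           seed = NULL) {
  seeds <- seed_stream(seed %||% sample.int(1e6, 1), 2 + 2 * n_enrolled)
  cohort <- simulate_cohort(n_enrolled, n_medicated, n_incomplete,
                            seed = seeds[1])
  analyzed <- filter_cohort(cohort)
  set.seed(seeds[2])
  n <- nrow(analyzed)
  covar <- tibble::tibble(
    id = analyzed$id,
    mass = analyzed$mass,
    sbp = rnorm(n, 135, 12),
    pulse_pressure = pmax(30, rnorm(n, 61, 8)),
    vo2_abs = pmax(800, rnorm(n, 2100, 350)),
    rer = rnorm(n, 1.13, 0.08),
    bpm_breaths = exp(rnorm(n, log(41), 0.2)),
    hr_max = rnorm(n, 170, 6.3),
    time_to_exhaustion = pmax(300, rnorm(n, 842, 140))
  )
  covar$dbp <- covar$sbp - covar$pulse_pressure

  rows <- purrr::map(seq_len(n), function(i) {
    idx <- match(analyzed$id[i], cohort$id)
    s_ibi <- seeds[2 + idx]
    s_art <- seeds[2 + n_enrolled + idx]
    mean_rr <- max(600, rnorm_seeded(s_ibi, mean_rr_mean, mean_rr_sd))
    jit <- exp(rnorm(2, 0, 0.2)) # amplitude jitter (seeded via s_ibi above)
    raw <- simulate_ibi(
      mean_rr = mean_rr,
      amp_lf = sqrt(2 * lf_power) * jit[1],
      amp_hf = sqrt(2 * hf_power) * jit[2],
      noise_sd = noise_sd, duration = 600, seed = NULL
    )
    corrupted <- inject_artifacts(raw, "spike", rate = artifact_rate,
                                  magnitude = artifact_magnitude, seed = s_art)
    cleaned <- clean_ibi(corrupted)
    profile <- hrv_profile(cleaned$series)
    list(profile = dplyr::bind_cols(tibble::tibble(id = analyzed$id[i]), profile),
         report = dplyr::bind_cols(tibble::tibble(id = analyzed$id[i]),
                                   glance(cleaned$report)))
  })
  profiles <- purrr::map_dfr(rows, "profile")

  participants <- profiles |>
    dplyr::left_join(covar, by = "id") |>
    dplyr::mutate(
      rest_hr = .data$mean_hr,
      rpp = rate_pressure_product(.data$rest_hr, .data$sbp),
      map = mean_arterial_pressure(.data$sbp, .data$dbp),
      vo2peak_allometric = allometric_vo2(.data$vo2_abs, .data$mass)
    ) |>
    dplyr::select(-"pulse_pressure")

  list(
    participants = participants,
    cohort = cohort,
    artifact_reports = purrr::map_dfr(rows, "report")
  )
}

# one seeded normal draw that also seeds the stream used right after it
rnorm_seeded <- function(seed, mean, sd) {
  set.seed(as.integer(seed))
  rnorm(1, mean, sd)
}

#' Pairwise Bayesian correlation matrix
#'
#' One [bayes_cor()] fit per (row variable, column variable) pair, reported
#' as posterior-median rho with 95% HDI bounds, the HDI-overlap decision
#' and the effect-size label. No multiplicity adjustment is applied across
#' pairs: each interval is a marginal posterior statement, and readers
#' should weigh the number of pairs examined accordingly.
#'
#' @param data Screened participant tibble.
#' @param row_vars,col_vars Character vectors of column names.
#' @param mcmc An [mcmc_config()]; its seed fans out to one child seed per
#'   pair.
#' @param hdi_mass Interval mass.
#' @return A tibble, one row per pair: `row_var`, `col_var`, `rho`,
#'   `hdi_lower`, `hdi_upper`, `decision`, `effect_size`.
#' @examples
#' \donttest{
#' d <- simulate_bivariate(30, rho = 0.8, seed = 2)
#' bayes_correlation_matrix(d, "x", "y", mcmc_config(n_save = 1500, seed = 2))
#' }
#' @export
bayes_correlation_matrix <- function(data, row_vars, col_vars,
                                     mcmc = mcmc_config(), hdi_mass = 0.95) {
  vars <- unique(c(row_vars, col_vars))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  pairs <- tidyr::expand_grid(row_var = row_vars, col_var = col_vars) |>
    dplyr::filter(.data$row_var != .data$col_var)
  pair_seeds <- if (!is.null(mcmc$seed)) seed_stream(mcmc$seed, nrow(pairs)) else
    rep(list(NULL), nrow(pairs))
  purrr::pmap_dfr(list(pairs$row_var, pairs$col_var, seq_len(nrow(pairs))),
    function(rv, cv, k) {
      cfg <- mcmc
      cfg$seed <- if (is.null(mcmc$seed)) NULL else pair_seeds[[k]]
      fit <- bayes_cor(data, !!rlang::sym(rv), !!rlang::sym(cv),
                       mcmc = cfg, hdi_mass = hdi_mass)
      g <- glance(fit)
      tibble::tibble(
        row_var = rv, col_var = cv,
        rho = g$rho_median, hdi_lower = g$hdi_lower, hdi_upper = g$hdi_upper,
        decision = g$decision, effect_size = g$effect_size
      )
    })
}

#' Row-triplet layout for a correlation matrix report
#'
#' Reshapes a [bayes_correlation_matrix()] result into the conventional
#' report layout: for each row variable three rows — `rho`, `Upper 95%
#' HDI`, `Lower 95% HDI` — with one column per column variable.
#'
#' @param matrix_result A [bayes_correlation_matrix()] tibble.
#' @return A wide tibble with columns `row_var`, `statistic` and one column
#'   per `col_var`.
#' @export
correlation_report <- function(matrix_result) {
  matrix_result |>
    dplyr::select("row_var", "col_var", "rho",
                  upper = "hdi_upper", lower = "hdi_lower") |>
    tidyr::pivot_longer(c("rho", "upper", "lower"), names_to = "statistic") |>
    dplyr::mutate(statistic = dplyr::recode(.data$statistic,
      rho = "rho", upper = "Upper 95% HDI", lower = "Lower 95% HDI")) |>
    tidyr::pivot_wider(names_from = "col_var", values_from = "value") |>
    dplyr::arrange(factor(.data$row_var, levels = unique(matrix_result$row_var)))
}

#' Bayesian descriptive table
#'
#' Per-variable posterior medians of the mean and SD with 95% HDIs
#' ([bayes_describe()]) alongside the normality screen and the
#' log-transform annotation — the descriptive summary table of a study
#' report.
#'
#' @param data Participant tibble.
#' @param vars Character vector of column names (default: all numeric).
#' @param mcmc An [mcmc_config()]; seed fans out per variable.
#' @param alpha Normality-screen cutoff.
#' @return A tibble, one row per variable: posterior `mean` and `sd` with
#'   HDI bounds, `shapiro_p`, `skewness`, `excess_kurtosis`, `transformed`.
#' @examples
#' \donttest{
#' d <- tibble::tibble(a = rnorm(30, 870, 60))
#' bayes_describe_table(d, "a", mcmc_config(n_save = 1500, seed = 4))
#' }
#' @export
bayes_describe_table <- function(data, vars = NULL, mcmc = mcmc_config(),
                                 alpha = 0.05) {
  screened <- screen_variables(data, vars, alpha)
  vars <- screened$screens$variable
  var_seeds <- if (!is.null(mcmc$seed)) seed_stream(mcmc$seed, length(vars)) else
    rep(list(NULL), length(vars))
  purrr::map_dfr(seq_along(vars), function(k) {
    v <- vars[k]
    cfg <- mcmc
    cfg$seed <- if (is.null(mcmc$seed)) NULL else var_seeds[[k]]
    g <- glance(bayes_describe(screened$data, !!rlang::sym(v), mcmc = cfg))
    scr <- screened$screens[k, ]
    tibble::tibble(
      variable = v,
      mean = g$mu_median, mean_hdi_lower = g$mu_hdi_lower,
      mean_hdi_upper = g$mu_hdi_upper,
      sd = g$sigma_median, sd_hdi_lower = g$sigma_hdi_lower,
      sd_hdi_upper = g$sigma_hdi_upper,
      shapiro_p = scr$shapiro_p, skewness = scr$skewness,
      excess_kurtosis = scr$excess_kurtosis,
      transformed = scr$transformed
    )
  })
}
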