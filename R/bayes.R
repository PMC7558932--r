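#' MCMC run configuration
#'
#' Settings for the component-wise random-walk Metropolis sampler: number
#' of chains, adaptation steps (proposal scales tuned toward a 0.2–0.5
#' acceptance rate, then frozen), burn-in steps (discarded), thinning
#' interval and the total number of saved draws across chains. The default
#' configuration (3 chains, 500 adapt, 500 burn-in, thin 10, 20,000 saved)
#' matches common practice for this model class. The saved total is split
#' evenly across chains with any remainder assigned to chain 1; set
#' `per_chain = TRUE` to save `n_save` draws in every chain instead.
#'
#' @param n_chains Number of chains.
#' @param adapt Adaptation steps per chain.
#' @param burn_in Burn-in steps per chain.
#' @param thin Thinning interval (every `thin`-th post-burn-in draw kept).
#' @param n_save Total saved draws (across chains unless `per_chain`).
#' @param per_chain Interpret `n_save` per chain.
#' @param seed Optional integer master seed; per-chain seeds are derived
#'   with [seed_stream()].
#' @return A list of class `mcmc_config`.
#' @examples
#' mcmc_config(n_save = 2000, seed = 1)
#' @export
mcmc_config <- function(n_chains = 3, adapt = 500, burn_in = 500, thin = 10,
                        n_save = 20000, per_chain = FALSE, seed = NULL) {
  stopifnot(n_chains >= 1, adapt >= 0, burn_in >= 0, thin >= 1, n_save >= n_chains)
  structure(
    list(n_chains = as.integer(n_chains), adapt = as.integer(adapt),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         n_save = as.integer(n_save), per_chain = isTRUE(per_chain),
         seed = seed),
    class = "mcmc_config"
  )
}

# per-chain saved-draw quotas; remainder goes to chain 1
chain_quotas <- function(cfg) {
  if (cfg$per_chain) return(rep(cfg$n_save, cfg$n_chains))
  base <- cfg$n_save %/% cfg$n_chains
  rem <- cfg$n_save %% cfg$n_chains
  q <- rep(base, cfg$n_chains)
  q[1] <- q[1] + rem
  q
}

run_chains <- function(cfg, quotas, runner) {
  seeds <- if (!is.null(cfg$seed)) seed_stream(cfg$seed, cfg$n_chains) else NULL
  purrr::map2_dfr(seq_len(cfg$n_chains), quotas, function(ch, q) {
    if (!is.null(seeds)) set.seed(seeds[ch])
    draws <- runner(q)
    dplyr::bind_cols(tibble::tibble(chain = ch, iter = seq_len(nrow(draws))),
                     tibble::as_tibble(draws, .name_repair = "minimal"))
  })
}

#' Bayesian estimation of a bivariate correlation
#'
#' Fits the bivariate-normal model
#' \deqn{(x_i, y_i) \sim N_2\big((\mu_1, \mu_2),\ \Sigma(\sigma_1, \sigma_2,
#' \rho)\big)}
#' with broad data-scaled priors — \eqn{\mu_j \sim N(\bar x_j, (100 s_j)^2)},
#' \eqn{\sigma_j \sim U(s_j/1000, 1000 s_j)}, \eqn{\rho \sim U(-1, 1)} —
#' by component-wise random-walk Metropolis in the transformed coordinates
#' \eqn{(\mu_1, \mu_2, \log\sigma_1, \log\sigma_2, \mathrm{atanh}\,\rho)}.
#' The association estimate is the posterior median of \eqn{\rho} with its
#' 95% highest-density interval; the association is called `"credible"`
#' only when that interval excludes zero, otherwise `"unclear"`.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy evaluation) of the paired variables.
#' @param mcmc An [mcmc_config()].
#' @param hdi_mass Posterior mass of the reported interval.
#' @return An object of class `hrv_bcor` with elements `draws` (tibble:
#'   `chain`, `iter`, `mu1`, `mu2`, `sigma1`, `sigma2`, `rho`), `data`,
#'   `hdi_mass` and the input labels. Methods: [tidy()] (per-parameter
#'   posterior medians, HDIs and convergence diagnostics), [glance()]
#'   (one-row: `rho_median`, HDI, decision, effect-size label),
#'   [autoplot()] (posterior of \eqn{\rho}), [ppc_ellipse()] /
#'   [plot_ppc()] (posterior predictive check).
#' @examples
#' d <- simulate_bivariate(50, rho = 0.7, seed = 1)
#' fit <- bayes_cor(d, x, y, mcmc = mcmc_config(n_save = 1500, seed = 1))
#' glance(fit)
#' @export
bayes_cor <- function(data, x, y, mcmc = mcmc_config(), hdi_mass = 0.95) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  if (length(xv) < 3) stop("need at least 3 pairs")
  if (anyNA(xv) || anyNA(yv) || !all(is.finite(c(xv, yv)))) {
    stop("non-finite values in input")
  }
  sx <- sd(xv); sy <- sd(yv)
  if (sx == 0 || sy == 0) stop("zero-variance input: correlation undefined")
  r <- stats::cor(xv, yv)
  if (abs(r) > 1 - 1e-12) stop("perfectly collinear input: degenerate likelihood")

  n <- length(xv)
  suff <- c(n, sum(xv), sum(yv), sum(xv^2), sum(yv^2), sum(xv * yv))
  prior <- c(mean(xv), 100 * sx, mean(yv), 100 * sy,
             sx / 1000, 1000 * sx, sy / 1000, 1000 * sy)
  init <- c(mean(xv), mean(yv), log(sx), log(sy), atanh(r))
  init_scale <- 2.4 * c(sx / sqrt(n), sy / sqrt(n),
                        sqrt(0.5 / n), sqrt(0.5 / n), 1 / sqrt(n))

  draws <- run_chains(mcmc, chain_quotas(mcmc), function(q) {
    m <- run_chain_bicor(suff, prior, init, init_scale,
                         mcmc$adapt, mcmc$burn_in, mcmc$thin, q)
    colnames(m) <- c("mu1", "mu2", "sigma1", "sigma2", "rho")
    m
  })
  structure(
    list(draws = draws,
         data = tibble::tibble(x = xv, y = yv),
         x_name = rlang::as_name(rlang::enquo(x)),
         y_name = rlang::as_name(rlang::enquo(y)),
         hdi_mass = hdi_mass, mcmc = mcmc),
    class = "hrv_bcor"
  )
}

#' Bayesian descriptive posterior for one variable
#'
#' Normal likelihood with the same broad data-scaled prior family as
#' [bayes_cor()]; reports posterior medians and highest-density intervals
#' of the mean and standard deviation, the machinery behind Bayesian
#' descriptive tables.
#'
#' @param data A data frame.
#' @param x Column (tidy evaluation).
#' @inheritParams bayes_cor
#' @return An object of class `hrv_bdesc` with a `draws` tibble (`chain`,
#'   `iter`, `mu`, `sigma`); [tidy()] gives per-parameter summaries.
#' @examples
#' d <- tibble::tibble(v = rnorm(50, 873, 59))
#' tidy(bayes_describe(d, v, mcmc = mcmc_config(n_save = 1500, seed = 1)))
#' @export
bayes_describe <- function(data, x, mcmc = mcmc_config(), hdi_mass = 0.95) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  if (length(xv) < 2) stop("need at least 2 observations")
  if (anyNA(xv) || !all(is.finite(xv))) stop("non-finite values in input")
  sx <- sd(xv)
  if (sx == 0) stop("zero-variance input")
  n <- length(xv)
  suff <- c(n, sum(xv), sum(xv^2))
  prior <- c(mean(xv), 100 * sx, sx / 1000, 1000 * sx)
  init <- c(mean(xv), log(sx))
  init_scale <- 2.4 * c(sx / sqrt(n), sqrt(0.5 / n))

  draws <- run_chains(mcmc, chain_quotas(mcmc), function(q) {
    m <- run_chain_uninorm(suff, prior, init, init_scale,
                           mcmc$adapt, mcmc$burn_in, mcmc$thin, q)
    colnames(m) <- c("mu", "sigma")
    m
  })
  structure(
    list(draws = draws, data = xv,
         x_name = rlang::as_name(rlang::enquo(x)),
         hdi_mass = hdi_mass, mcmc = mcmc),
    class = "hrv_bdesc"
  )
}

param_summary <- function(draws, params, mass) {
  purrr::map_dfr(params, function(p) {
    v <- draws[[p]]
    h <- hdi(v, mass)
    by_chain <- split(v, draws$chain)
    e <- sum(vapply(by_chain, ess, numeric(1)))
    tibble::tibble(
      term = p,
      estimate = median(v),
      hdi_lower = h$lower,
      hdi_upper = h$upper,
      psrf = if (length(by_chain) >= 2) psrf(by_chain) else NA_real_,
      ess = e,
      mcse = sd(v) / sqrt(e)
    )
  })
}

#' @exportS3Method generics::tidy
tidy.hrv_bcor <- function(x, ...) {
  param_summary(x$draws, c("mu1", "mu2", "sigma1", "sigma2", "rho"), x$hdi_mass)
}

#' @exportS3Method generics::glance
glance.hrv_bcor <- function(x, ...) {
  h <- hdi(x$draws$rho, x$hdi_mass)
  m <- median(x$draws$rho)
  tibble::tibble(
    rho_median = m,
    hdi_lower = h$lower,
    hdi_upper = h$upper,
    decision = hdi_decision(h$lower, h$upper),
    effect_size = classify_effect_size(m),
    n = nrow(x$data),
    n_draws = nrow(x$draws)
  )
}

#' @exportS3Method generics::tidy
tidy.hrv_bdesc <- function(x, ...) {
  param_summary(x$draws, c("mu", "sigma"), x$hdi_mass)
}

#' @exportS3Method generics::glance
glance.hrv_bdesc <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    mu_median = s$estimate[s$term == "mu"],
    mu_hdi_lower = s$hdi_lower[s$term == "mu"],
    mu_hdi_upper = s$hdi_upper[s$term == "mu"],
    sigma_median = s$estimate[s$term == "sigma"],
    sigma_hdi_lower = s$hdi_lower[s$term == "sigma"],
    sigma_hdi_upper = s$hdi_upper[s$term == "sigma"],
    n = length(x$data),
    n_draws = nrow(x$draws)
  )
}

#' @export
print.hrv_bcor <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Bayesian correlation %s ~ %s: rho = %.3f, %.0f%% HDI (%.3f, %.3f), %s (%s)\n",
    x$x_name, x$y_name, g$rho_median, 100 * x$hdi_mass,
    g$hdi_lower, g$hdi_upper, g$decision, g$effect_size
  ))
  invisible(x)
}

#' @export
print.hrv_bdesc <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Bayesian description of %s: mean %.3g (%.3g-%.3g), SD %.3g (%.3g-%.3g)\n",
    x$x_name, g$mu_median, g$mu_hdi_lower, g$mu_hdi_upper,
    g$sigma_median, g$sigma_hdi_lower, g$sigma_hdi_upper
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hrv_bcor <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$draws, ggplot2::aes(.data$rho)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = c(g$hdi_lower, g$hdi_upper), linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red3") +
    ggplot2::labs(
      x = expression(rho), y = "Posterior density",
      title = sprintf("%s ~ %s: rho = %.3f [%s]", object$x_name,
                      object$y_name, g$rho_median, g$decision)
    )
}
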