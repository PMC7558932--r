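#' Posterior predictive ellipse check
#'
#' Retrospective model check for the bivariate-normal correlation model:
#' the posterior-median parameters \eqn{(\mu, \Sigma)} define, for each
#' credibility level, the bivariate-normal ellipse
#' \eqn{(z - \mu)^\top \Sigma^{-1} (z - \mu) \le \chi^2_2(level)}; the
#' check reports the fraction of observed points inside. If the model fits,
#' containment should be close to the level; the heuristic pass rule is
#' containment at least \eqn{1 - 2(1 - level)} (e.g. 0.90 at level 0.95),
#' tolerant of small-sample fluctuation.
#'
#' @param fit An [bayes_cor()] fit.
#' @param levels Credibility levels of the ellipses.
#' @return A tibble with one row per level: `level`, `containment`, `pass`,
#'   and the ellipse parameters (`mu1`, `mu2`, semi-axes `a`, `b`, rotation
#'   `angle` in radians).
#' @examples
#' d <- simulate_bivariate(200, rho = 0.6, seed = 3)
#' fit <- bayes_cor(d, x, y, mcmc = mcmc_config(n_save = 1500, seed = 3))
#' ppc_ellipse(fit)
#' @export
ppc_ellipse <- function(fit, levels = 0.95) {
  if (!inherits(fit, "hrv_bcor")) stop("`fit` must be a bayes_cor() result")
  d <- fit$draws
  mu <- c(median(d$mu1), median(d$mu2))
  s1 <- median(d$sigma1); s2 <- median(d$sigma2); r <- median(d$rho)
  sigma <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
  ev <- eigen(sigma, symmetric = TRUE)
  z <- cbind(fit$data$x - mu[1], fit$data$y - mu[2])
  d2 <- rowSums((z %*% ev$vectors)^2 %*% diag(1 / ev$values))
  purrr::map_dfr(levels, function(lv) {
    q <- qchisq(lv, df = 2)
    contained <- mean(d2 <= q)
    tibble::tibble(
      level = lv,
      containment = contained,
      pass = contained >= 1 - 2 * (1 - lv),
      mu1 = mu[1], mu2 = mu[2],
      a = sqrt(q * ev$values[1]), b = sqrt(q * ev$values[2]),
      angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    )
  })
}

#' Posterior predictive scatter plot with model ellipses
#'
#' @inheritParams ppc_ellipse
#' @return A ggplot object: the data scatter with the posterior-median
#'   model ellipses superimposed.
#' @export
plot_ppc <- function(fit, levels = c(0.5, 0.95)) {
  ell <- ppc_ellipse(fit, levels)
  theta <- seq(0, 2 * pi, length.out = 181)
  paths <- purrr::pmap_dfr(ell, function(level, mu1, mu2, a, b, angle, ...) {
    xe <- a * cos(theta); ye <- b * sin(theta)
    tibble::tibble(
      level = factor(level),
      x = mu1 + xe * cos(angle) - ye * sin(angle),
      y = mu2 + xe * sin(angle) + ye * cos(angle)
    )
  })
  ggplot2::ggplot(fit$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(group = .data$level, colour = .data$level)) +
    ggplot2::labs(x = fit$x_name, y = fit$y_name, colour = "Level",
                  title = "Posterior predictive ellipse check")
}
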