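#' Shortest (highest-density) posterior interval
#'
#' The shortest contiguous interval over the sorted draws that contains
#' \eqn{\lceil \mathrm{mass} \cdot n \rceil} of them. For a unimodal
#' posterior this is the highest-density interval: every point inside is
#' more credible than any point outside. Ties between equally short windows
#' are broken toward the lowest window.
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param mass Interval mass (default 0.95).
#' @return A one-row tibble: `lower`, `upper`, `mass`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop("HDI needs at least 100 draws")
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(tibble::tibble(lower = x[1], upper = x[n], mass = mass))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths) # which.min takes the first minimum: lowest window
  tibble::tibble(lower = x[i], upper = x[i + k - 1], mass = mass)
}

#' Gelman–Rubin potential scale reduction factor
#'
#' \eqn{\sqrt{((n-1)/n \cdot W + B/n) / W}} with \eqn{W} the mean
#' within-chain variance and \eqn{B/n} the between-chain variance of the
#' chain means. Values near 1 indicate the chains have mixed into the same
#' distribution; values well above 1.1 indicate non-convergence.
#'
#' @param chains A list of numeric vectors (one per chain, equal lengths),
#'   or a matrix with one column per chain.
#' @return The PSRF (scalar).
#' @examples
#' psrf(list(rnorm(500), rnorm(500)))
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("PSRF needs at least 2 chains")
  n <- min(lengths(chains))
  if (n < 2) stop("chains too short")
  chains <- lapply(chains, function(x) x[seq_len(n)]) # align unequal quotas
  w <- mean(vapply(chains, var, numeric(1)))
  b_over_n <- var(vapply(chains, mean, numeric(1)))
  if (w == 0) return(if (b_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Effective sample size and Monte Carlo standard error
#'
#' `ess()` uses the initial-positive-sequence estimator: autocorrelations
#' are summed in adjacent pairs \eqn{\Gamma_m = \rho_{2m} + \rho_{2m+1}}
#' until the first non-positive pair, giving the integrated autocorrelation
#' time \eqn{\tau = 2\sum_m \Gamma_m - 1} and \eqn{ESS = n/\tau} (capped at
#' `n`). `mcse()` is the posterior standard deviation divided by
#' \eqn{\sqrt{ESS}}.
#'
#' @param draws Numeric vector of draws from one chain.
#' @return A scalar.
#' @examples
#' ess(rnorm(1000))
#' @export
ess <- function(draws) {
  n <- length(draws)
  if (n < 4) stop("too few draws for an ESS estimate")
  v <- var(draws)
  if (v == 0) return(1)
  # autocovariance via FFT
  x <- draws - mean(draws)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m
  rho <- ac / ac[1]
  tau <- 1
  m_idx <- 1
  while (2 * m_idx + 1 <= n) {
    gamma <- rho[2 * m_idx] + rho[2 * m_idx + 1]
    if (gamma <= 0) break
    tau <- tau + 2 * gamma
    m_idx <- m_idx + 1
  }
  min(n, n / tau)
}

#' @param draws Numeric vector of draws.
#' @rdname ess
#' @export
mcse <- function(draws) {
  sd(draws) / sqrt(ess(draws))
}
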