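#' Normality screen for one variable
#'
#' Shapiro–Wilk test (Royston approximation via [stats::shapiro.test()]),
#' bias-corrected sample skewness and excess kurtosis (type-2 estimators as
#' in mainstream statistics software). A variable is flagged non-normal at
#' `shapiro_p <= alpha` and too kurtotic when `|excess_kurtosis| > 3`.
#'
#' @param x Numeric vector, `3 <= n <= 5000`.
#' @param alpha Significance cutoff for the Shapiro–Wilk p-value.
#' @return A one-row tibble: `n`, `shapiro_w`, `shapiro_p`, `skewness`,
#'   `excess_kurtosis`, `too_kurtotic`, `normal`.
#' @examples
#' normality_screen(rnorm(50))
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("normality screen needs at least 3 observations")
  # shapiro.test caps at 5000; use evenly spaced order statistics beyond that
  sw_x <- if (n > 5000) sort(x)[round(seq(1, n, length.out = 5000))] else x
  sw <- shapiro.test(sw_x)
  tibble::tibble(
    n = n,
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    skewness = if (n >= 3) e1071::skewness(x, type = 2) else NA_real_,
    excess_kurtosis = if (n >= 4) e1071::kurtosis(x, type = 2) else NA_real_,
    too_kurtotic = if (n >= 4) abs(e1071::kurtosis(x, type = 2)) > 3 else NA,
    normal = sw$p.value > alpha
  )
}

#' Log-transform a variable when it fails the normality screen
#'
#' Applies the natural log if and only if the raw screen rejects normality
#' (`shapiro_p <= alpha`), then re-screens, mirroring the screen-transform-
#' rescreen workflow used before Gaussian-likelihood modelling.
#'
#' @param x Numeric vector (positive when the transform triggers).
#' @param alpha Screen cutoff.
#' @return A list with `values` (possibly transformed), `transformed`
#'   (logical), `screen_raw` and `screen_final` (tibbles from
#'   [normality_screen()]).
#' @examples
#' out <- log_transform_if_needed(rlnorm(60))
#' out$transformed
#' @export
log_transform_if_needed <- function(x, alpha = 0.05) {
  raw <- normality_screen(x, alpha)
  if (raw$shapiro_p > alpha) {
    return(list(values = x, transformed = FALSE,
                screen_raw = raw, screen_final = raw))
  }
  if (any(x <= 0)) {
    stop("log transform triggered but values are not all positive")
  }
  lx <- log(x)
  list(values = lx, transformed = TRUE,
       screen_raw = raw, screen_final = normality_screen(lx, alpha))
}

#' Screen every analysis variable of a participant table
#'
#' Runs [normality_screen()] and the conditional log transform on each
#' named column; returns the screened table (columns replaced in place when
#' transformed) and the per-variable screen report.
#'
#' @param data Participant tibble.
#' @param vars Character vector of column names (default: all numeric
#'   columns).
#' @param alpha Screen cutoff.
#' @return A list with `data` (screened tibble) and `screens` (tibble, one
#'   row per variable with the raw screen and a `transformed` flag).
#' @export
screen_variables <- function(data, vars = NULL, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  out <- data
  screens <- purrr::map_dfr(vars, function(v) {
    res <- log_transform_if_needed(data[[v]], alpha)
    out[[v]] <<- res$values
    dplyr::bind_cols(tibble::tibble(variable = v, transformed = res$transformed),
                     res$screen_raw)
  })
  list(data = out, screens = screens)
}
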