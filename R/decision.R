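#' Effect-size label for a correlation
#'
#' Cohen's conventional bins applied to the magnitude of the posterior
#' median correlation: 0.1–0.29 small, 0.3–0.49 medium, above 0.5 large;
#' below 0.1 negligible.
#'
#' @param rho Correlation estimate(s), in `[-1, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_effect_size(c(0.05, 0.35, -0.68))
#' @export
classify_effect_size <- function(rho) {
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1")
  a <- abs(rho)
  dplyr::case_when(
    a < 0.1 ~ "negligible",
    a < 0.3 ~ "small",
    a < 0.5 ~ "medium",
    TRUE ~ "large"
  )
}

#' HDI overlap decision rule
#'
#' Under the posterior, the correlation is equally likely to fall anywhere
#' inside its highest-density interval, so an interval that overlaps zero
#' is not evidence of association. The association is `"credible"` only
#' when both interval bounds share a sign (the interval excludes zero),
#' otherwise `"unclear"`.
#'
#' @param lower,upper HDI bounds (vectorised).
#' @return Character vector, `"credible"` or `"unclear"`.
#' @examples
#' hdi_decision(0.001, 0.918) # credible
#' hdi_decision(-0.378, 0.793) # unclear
#' @export
hdi_decision <- function(lower, upper) {
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  ifelse(lower * upper > 0, "credible", "unclear")
}
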