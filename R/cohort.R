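#' Simulate an enrolled cohort with exclusion flags
#'
#' Generates an enrolment table for a small observational study: per
#' participant age, body mass and height, plus the two exclusion flags that
#' drive the analyzed count — blood-pressure medication use and completion
#' of the testing procedure. Defaults emulate a cohort of twelve enrolled
#' middle-aged women of whom two report BP medication and two do not
#' complete testing, leaving eight analyzable participants.
#'
#' @param n_enrolled Number enrolled.
#' @param n_medicated Number on BP medication (excluded).
#' @param n_incomplete Number not completing testing (excluded; disjoint
#'   from the medicated).
#' @param age_mean,age_sd,mass_mean,mass_sd,height_mean,height_sd
#'   Anthropometry distribution parameters (years, kg, cm).
#' @param seed Optional integer seed.
#' @return A tibble: `id`, `age`, `mass`, `height`, `on_bp_medication`,
#'   `completed`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(filter_cohort(cohort)) # 8
#' @export
simulate_cohort <- function(n_enrolled = 12, n_medicated = 2, n_incomplete = 2,
                            age_mean = 53.9, age_sd = 5.7,
                            mass_mean = 71.8, mass_sd = 10.1,
                            height_mean = 164.4, height_sd = 6.2,
                            seed = NULL) {
  stopifnot(n_enrolled >= 1, n_medicated >= 0, n_incomplete >= 0,
            n_medicated + n_incomplete <= n_enrolled)
  if (!is.null(seed)) set.seed(as.integer(seed))
  excluded <- sample.int(n_enrolled, n_medicated + n_incomplete)
  tibble::tibble(
    id = sprintf("P%02d", seq_len(n_enrolled)),
    age = pmax(30, rnorm(n_enrolled, age_mean, age_sd)),
    mass = pmax(40, rnorm(n_enrolled, mass_mean, mass_sd)),
    height = rnorm(n_enrolled, height_mean, height_sd),
    on_bp_medication = seq_len(n_enrolled) %in% excluded[seq_len(n_medicated)],
    completed = !(seq_len(n_enrolled) %in%
                    excluded[n_medicated + seq_len(n_incomplete)])
  )
}

#' Apply the cohort exclusion rules
#'
#' Keeps participants who are not on blood-pressure medication and
#' completed the testing procedure.
#'
#' @param cohort A tibble with logical `on_bp_medication` and `completed`
#'   columns (see [simulate_cohort()]).
#' @return The analyzable subset.
#' @export
filter_cohort <- function(cohort) {
  req <- c("on_bp_medication", "completed")
  if (!all(req %in% names(cohort))) {
    stop("cohort table needs columns: ", paste(req, collapse = ", "))
  }
  dplyr::filter(cohort, !.data$on_bp_medication, .data$completed)
}
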