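#' Blood-pressure and aerobic covariate formulas
#'
#' `rate_pressure_product()` is the myocardial-work index
#' \eqn{RPP = HR \times SBP} (mmHg·bpm). `mean_arterial_pressure()` is
#' \eqn{MAP = (SBP - DBP)/3 + DBP} (mmHg). `allometric_vo2()` scales
#' absolute oxygen uptake by body mass to the 0.67 power,
#' \eqn{VO_2 / m^{0.67}} (mL·kg^-0.67·min^-1), removing the body-size
#' dependence of aerobic capacity.
#'
#' @param hr Resting heart rate, bpm (> 0).
#' @param sbp,dbp Systolic and diastolic pressure, mmHg (`sbp > dbp > 0`).
#' @param vo2_abs Absolute peak oxygen uptake, mL/min (> 0).
#' @param mass Body mass, kg (> 0).
#' @return Numeric vector (vectorised over inputs).
#' @examples
#' rate_pressure_product(70, 130) # 9100
#' mean_arterial_pressure(120, 80) # 93.33
#' allometric_vo2(2000, 70)
#' @export
rate_pressure_product <- function(hr, sbp) {
  if (any(hr <= 0) || any(sbp <= 0)) stop("hr and sbp must be positive")
  hr * sbp
}

#' @rdname rate_pressure_product
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("dbp must be positive")
  if (any(sbp <= dbp)) stop("sbp must exceed dbp")
  (sbp - dbp) / 3 + dbp
}

#' @rdname rate_pressure_product
#' @export
allometric_vo2 <- function(vo2_abs, mass) {
  if (any(vo2_abs <= 0) || any(mass <= 0)) stop("vo2_abs and mass must be positive")
  vo2_abs / mass^0.67
}
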