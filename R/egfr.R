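#' CKD-EPI (2009) creatinine eGFR
#'
#' Estimated glomerular filtration rate from serum creatinine using the 2009
#' CKD-EPI creatinine equation. The race coefficient is omitted (the data
#' model carries no race variable). Creatinine is converted internally at
#' 1 mg/dL = 88.4 umol/L.
#'
#' @param scr_umol serum creatinine, umol/L (> 0); vectorised
#' @param age age in years (>= 18)
#' @param sex 1 = male, 0 = female
#' @return eGFR in mL/min/1.73 m^2
#' @examples
#' egfr_ckdepi(70.7, 60, 0)  # ~80.1
#' @export
egfr_ckdepi <- function(scr_umol, age, sex) {
  n <- max(length(scr_umol), length(age), length(sex))
  scr_umol <- rep_len(scr_umol, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(!is.finite(scr_umol)) || any(scr_umol <= 0))
    stop("egfr_ckdepi: serum creatinine must be positive and finite")
  if (any(!is.finite(age)) || any(age < 18))
    stop("egfr_ckdepi: age must be >= 18 years")
  if (!all(sex %in% c(0, 1)))
    stop("egfr_ckdepi: sex must be coded 1 (male) / 0 (female)")
  scr <- scr_umol / 88.4
  kappa <- ifelse(sex == 1, 0.9, 0.7)
  alpha <- ifelse(sex == 1, -0.411, -0.329)
  v <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age
  v * ifelse(sex == 1, 1, 1.018)
}

#' Invert CKD-EPI: creatinine consistent with a target eGFR
#'
#' Back-solves serum creatinine from eGFR, age and sex by bisection on the
#' CKD-EPI equation (monotone decreasing in creatinine), to a tolerance of
#' 0.01 umol/L. Used by the synthetic generator so sampled eGFR values map to
#' creatinine baselines that reproduce them under [egfr_ckdepi()].
#'
#' @param egfr target eGFR, mL/min/1.73 m^2 (> 0); vectorised
#' @param age,sex as in [egfr_ckdepi()]
#' @param tol bisection tolerance, umol/L
#' @return serum creatinine, umol/L
#' @export
creatinine_from_egfr <- function(egfr, age, sex, tol = 0.01) {
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(!is.finite(egfr)) || any(egfr <= 0))
    stop("creatinine_from_egfr: eGFR must be positive")
  lo <- rep(5, n); hi <- rep(5000, n)
  # eGFR(lo) > target > eGFR(hi) for any physiologic target
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    too_high <- egfr_ckdepi(mid, age, sex) > egfr  # creatinine still too low
    lo <- ifelse(too_high, mid, lo)
    hi <- ifelse(too_high, hi, mid)
  }
  (lo + hi) / 2
}
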