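# Outcome adjudication: kidney failure = long-term RRT or eGFR < 15 sustained
# for at least 90 days; death without kidney failure competes; administrative
# censoring 5 years after the landmark.

# First day d (d > from_day) at which `values` drops below `threshold` and
# stays below through a confirmatory measurement at day >= d + sustain_days,
# with no intervening value at or above threshold. NA when never sustained.
sustained_low_onset <- function(day, values, threshold, from_day,
                                sustain_days = 90) {
  keep <- day > from_day
  day <- day[keep]; values <- values[keep]
  m <- length(day)
  if (!m) return(NA_real_)
  j <- 1L
  while (j <= m) {
    if (values[j] < threshold) {
      broken <- FALSE; confirmed <- FALSE
      k <- j + 1L
      while (k <= m) {
        if (values[k] >= threshold) { broken <- TRUE; break }
        if (day[k] >= day[j] + sustain_days) { confirmed <- TRUE; break }
        k <- k + 1L
      }
      if (confirmed) return(day[j])
      if (broken) { j <- k + 1L; next }  # resume after the break
      return(NA_real_)                    # series ended unconfirmed
    }
    j <- j + 1L
  }
  NA_real_
}

adjudicate_impl <- function(series, rrt_day, death_day, landmark_day,
                            horizon_years, age_entry, sex, threshold,
                            scan_from = -Inf) {
  series <- check_series(series)
  if (!is.na(death_day) && death_day <= landmark_day)
    return(list(event = "excluded", reason = "death_before_landmark",
                time_years = NA_real_))
  if (!is.na(rrt_day) && rrt_day <= landmark_day)
    return(list(event = "excluded", reason = "rrt_before_landmark",
                time_years = NA_real_))
  egfr <- egfr_ckdepi(series$scr, age_entry + series$day / 365.25, sex)
  # established sustained-low state before the landmark -> exclusion
  pre <- sustained_low_onset(series$day, egfr, threshold, from_day = scan_from)
  if (!is.na(pre) && pre <= landmark_day)
    return(list(event = "excluded", reason = "sustained_low_before_landmark",
                time_years = NA_real_))
  horizon_day <- landmark_day + horizon_years * 365.25
  low_day <- if (!is.na(pre)) pre else NA_real_  # pre > landmark when not NA
  kf_day <- suppressWarnings(min(c(rrt_day, low_day), na.rm = TRUE))
  if (!is.finite(kf_day)) kf_day <- NA_real_
  # first event in time order within the horizon; ties adjudicated as
  # kidney failure
  if (!is.na(kf_day) && kf_day <= horizon_day &&
      (is.na(death_day) || kf_day <= death_day))
    return(list(event = "kidney_failure", reason = NA_character_,
                time_years = (kf_day - landmark_day) / 365.25))
  if (!is.na(death_day) && death_day <= horizon_day)
    return(list(event = "death", reason = NA_character_,
                time_years = (death_day - landmark_day) / 365.25))
  list(event = "censored", reason = NA_character_, time_years = horizon_years)
}

#' Adjudicate the 5-year kidney failure / death / censored outcome
#'
#' Kidney failure occurs at the first post-landmark day where long-term RRT
#' starts, or where eGFR falls below 15 mL/min/1.73 m^2 and every subsequent
#' measurement through at least 90 days later stays below 15 (a confirmatory
#' measurement at >= 90 days is required; deaths during an unconfirmed low
#' period are adjudicated as death). Death before kidney failure is the
#' competing event; otherwise the subject is censored at `horizon_years`.
#' Time is measured from the landmark in years (days / 365.25).
#'
#' A death or RRT start at or before the landmark, or a sustained low period
#' established before the landmark, returns `event = "excluded"` with a
#' reason; [build_landmark_cohort()] consumes these.
#'
#' @param series one patient's labs: data.frame(day, scr)
#' @param rrt_day day long-term RRT started, or `NA`
#' @param death_day day of death, or `NA`
#' @param landmark_day follow-up origin (default 730 = 2 years)
#' @param horizon_years administrative censoring horizon (default 5)
#' @param age_entry age in years at day 0 (eGFR is age-dependent)
#' @param sex 1 male / 0 female
#' @return list(event, reason, time_years)
#' @export
adjudicate_outcome <- function(series, rrt_day = NA, death_day = NA,
                               landmark_day = 730, horizon_years = 5,
                               age_entry, sex) {
  adjudicate_impl(series, rrt_day, death_day, landmark_day, horizon_years,
                  age_entry, sex, threshold = 15)
}

#' Adjudicate the 30% sustained eGFR decline sensitivity endpoint
#'
#' As [adjudicate_outcome()] with the absolute eGFR < 15 threshold replaced
#' by 0.70 x the landmark eGFR (last measurement at or before the landmark);
#' the 90-day sustainment rule is unchanged and long-term RRT still counts.
#'
#' @inheritParams adjudicate_outcome
#' @export
adjudicate_decline30 <- function(series, rrt_day = NA, death_day = NA,
                                 landmark_day = 730, horizon_years = 5,
                                 age_entry, sex) {
  series <- check_series(series)
  pre <- series[series$day <= landmark_day, , drop = FALSE]
  if (!nrow(pre)) stop("no measurement at or before the landmark")
  i <- which.max(pre$day)
  egfr_lm <- egfr_ckdepi(pre$scr[i], age_entry + pre$day[i] / 365.25, sex)
  # the sustained rule only applies after the landmark: the threshold is
  # itself defined by the landmark value
  adjudicate_impl(series, rrt_day, death_day, landmark_day,
                  horizon_years, age_entry, sex,
                  threshold = 0.70 * egfr_lm, scan_from = landmark_day)
}
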