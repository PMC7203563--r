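#' Build the landmark analysis cohort
#'
#' Follow-up starts at the end of a 2-year observation window (the landmark,
#' day 730 by default) to avoid immortal time bias. Patients who die, start
#' long-term RRT, or establish a sustained eGFR < 15 before the landmark are
#' excluded, as are patients without any creatinine test. AKI exposure flags
#' are computed with [detect_aki()] over days `[0, landmark_day]`; the
#' landmark eGFR comes from the last creatinine at or before the landmark;
#' ACR (and its KDIGO proteinuria category) comes from the covariate table.
#' Outcomes are adjudicated with [adjudicate_outcome()] (or
#' [adjudicate_decline30()] when `endpoint = "decline30"`).
#'
#' @param patients data.frame: patient_id, age_years (at entry), sex
#'   (1 male / 0 female), acr_mg_g (NA = not tested), diagnosis, diabetes,
#'   sbp, dbp
#' @param labs data.frame: patient_id, day, scr_umol_l
#' @param events data.frame: patient_id, rrt_day, death_day (NA when absent)
#' @param config [aki_config()]
#' @param landmark_day landmark, days from entry
#' @param horizon_years administrative censoring horizon after the landmark
#' @param endpoint "kf15" (kidney failure: RRT or sustained eGFR < 15) or
#'   "decline30" (RRT or sustained 30% eGFR decline from landmark)
#' @return data.frame of one analysis-ready row per retained patient with
#'   attributes `exclusions` (named counts) and `landmark_day`
#' @export
build_landmark_cohort <- function(patients, labs, events,
                                  config = aki_config(),
                                  landmark_day = 730, horizon_years = 5,
                                  endpoint = c("kf15", "decline30")) {
  endpoint <- match.arg(endpoint)
  patients <- as.data.frame(patients)
  labs <- as.data.frame(labs)
  events <- as.data.frame(events)
  stopifnot(all(c("patient_id", "age_years", "sex") %in% names(patients)))
  labs_by_id <- split(labs[c("day", "scr_umol_l")], labs$patient_id)
  ev_idx <- match(patients$patient_id, events$patient_id)
  excl <- c(no_labs = 0L, death_before_landmark = 0L,
            rrt_before_landmark = 0L, sustained_low_before_landmark = 0L)
  rows <- vector("list", nrow(patients))
  iii_config <- config
  iii_config$criteria_enabled <- "iii"
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    lab <- labs_by_id[[as.character(pid)]]
    if (is.null(lab) || nrow(lab) == 0) {
      excl["no_labs"] <- excl["no_labs"] + 1L
      next
    }
    series <- data.frame(day = lab$day, scr = lab$scr_umol_l)
    series <- check_series(series)
    age0 <- patients$age_years[i]; sex <- patients$sex[i]
    rrt_day <- if (is.na(ev_idx[i])) NA_real_ else events$rrt_day[ev_idx[i]]
    death_day <- if (is.na(ev_idx[i])) NA_real_ else events$death_day[ev_idx[i]]
    adj <- if (endpoint == "kf15")
      adjudicate_outcome(series, rrt_day, death_day, landmark_day,
                         horizon_years, age_entry = age0, sex = sex)
    else
      adjudicate_decline30(series, rrt_day, death_day, landmark_day,
                           horizon_years, age_entry = age0, sex = sex)
    if (adj$event == "excluded") {
      excl[adj$reason] <- excl[adj$reason] + 1L
      next
    }
    obs <- series[series$day <= landmark_day, , drop = FALSE]
    if (!nrow(obs)) { excl["no_labs"] <- excl["no_labs"] + 1L; next }
    episodes <- detect_aki(series, window = c(0, landmark_day), config)
    flags <- classify_recurrence(episodes, config)
    # criterion-iii triggers are a subset of all-criteria triggers, so the
    # restricted pass is only needed when the full pass found something
    ep3 <- if (nrow(episodes) && "iii" %in% config$criteria_enabled)
      detect_aki(series, window = c(0, landmark_day), iii_config)
    else episodes[0, , drop = FALSE]
    j <- which.max(obs$day)
    egfr_lm <- egfr_ckdepi(obs$scr[j], age0 + obs$day[j] / 365.25, sex)
    acr <- if ("acr_mg_g" %in% names(patients)) patients$acr_mg_g[i] else NA
    rows[[i]] <- list(
      patient_id = pid,
      age_landmark = age0 + landmark_day / 365.25,
      sex = sex,
      egfr_landmark = egfr_lm,
      lnacr = if (is.na(acr)) NA_real_ else log(acr),
      proteinuria_cat = proteinuria_category(acr),
      diagnosis_cat = if ("diagnosis" %in% names(patients))
        as.character(patients$diagnosis[i]) else "not_recorded",
      diabetes = if ("diabetes" %in% names(patients))
        patients$diabetes[i] else NA,
      sbp = if ("sbp" %in% names(patients)) patients$sbp[i] else NA,
      dbp = if ("dbp" %in% names(patients)) patients$dbp[i] else NA,
      aki_2yr = flags$aki_2yr,
      aki_recurrent = flags$aki_recurrent,
      aki_stage_max = flags$aki_stage_max,
      aki_criterion_iii = as.integer(nrow(ep3) >= 1),
      event = adj$event,
      time_years = adj$time_years
    )
  }
  keep <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(keep)) as.data.frame(data.table::rbindlist(keep))
         else data.frame()
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "landmark_day") <- landmark_day
  out
}

#' KDIGO albuminuria category from ACR
#'
#' @param acr albumin:creatinine ratio, mg/g; `NA` = not tested
#' @return "severe" (> 300), "moderate" (30-300), "none_mild" (< 30) or
#'   "not_tested"
#' @export
proteinuria_category <- function(acr) {
  vapply(acr, function(a) {
    if (is.na(a)) "not_tested"
    else if (a > 300) "severe"
    else if (a >= 30) "moderate"
    else "none_mild"
  }, character(1))
}
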