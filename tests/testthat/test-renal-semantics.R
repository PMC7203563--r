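# CKD-EPI eGFR, the three-criterion AKI detector, outcome adjudication and
# landmark cohort construction.

test_that("egfr_ckdepi matches a hand evaluation of the piecewise formula", {
  # 0.8 mg/dL (= 70.72 umol/L), 60 y female: above the female knot
  hand <- 141 * (0.8 / 0.7)^(-1.209) * 0.993^60 * 1.018
  expect_equal(egfr_ckdepi(0.8 * 88.4, 60, 0), hand, tolerance = 1e-10)
  expect_lt(abs(egfr_ckdepi(70.7, 60, 0) - 80.1), 0.1)
  # male > female at equal creatinine/age; eGFR decreasing in creatinine
  expect_gt(egfr_ckdepi(120, 70, 1), egfr_ckdepi(120, 70, 0))
  expect_lt(egfr_ckdepi(240, 70, 1), egfr_ckdepi(120, 70, 1))
  expect_error(egfr_ckdepi(-1, 60, 0), "positive")
  expect_error(egfr_ckdepi(80, 10, 0), "18")
})

test_that("creatinine_from_egfr inverts CKD-EPI to within 0.1 eGFR units", {
  grid <- expand.grid(egfr = c(12, 20, 30, 45, 60, 90),
                      age = c(25, 50, 70, 88), sex = c(0, 1))
  scr <- creatinine_from_egfr(grid$egfr, grid$age, grid$sex)
  expect_true(all(abs(egfr_ckdepi(scr, grid$age, grid$sex) - grid$egfr) < 0.1))
})

test_that("reference_creatinine windows follow the stated lookbacks", {
  s <- series_df(c(0, 30, 60), c(100, 100, 160))
  r <- reference_creatinine(s, 60)
  expect_equal(r$ref_median, 100)
  expect_true(is.na(r$ref_min7) && is.na(r$ref_min48))

  r1 <- reference_creatinine(series_df(5, 100), 5)
  expect_true(all(is.na(unlist(r1))))

  s2 <- series_df(c(0, 59, 60), c(100, 120, 130))
  r2 <- reference_creatinine(s2, 60)
  expect_equal(r2$ref_median, 100)  # day 0 is 60 days prior, inside [8, 90]
  expect_equal(r2$ref_min7, 120)
  expect_equal(r2$ref_min48, 120)

  # fallback window when [8, 90] is empty
  s3 <- series_df(c(0, 120), c(90, 200))
  expect_equal(reference_creatinine(s3, 120)$ref_median, 90)
  expect_error(reference_creatinine(s, 45), "measurement")
})

test_that("detect_aki hand traces: criteria, ratio, stage, merging", {
  ep <- detect_aki(series_df(c(0, 30, 60), c(100, 100, 160)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$trigger_criterion, "i")
  expect_equal(ep$peak_ratio, 1.6)
  expect_equal(ep$stage, 1L)

  expect_equal(nrow(detect_aki(flat_series(seq(0, 730, 30)))), 0)

  ep3 <- detect_aki(series_df(c(0, 1), c(100, 130)))
  expect_equal(ep3$trigger_criterion, "iii")  # 30 > 26 but ratio 1.3 < 1.5
  expect_equal(ep3$stage, 1L)

  # ratio >= 3 or absolute creatinine >= 353.6 -> stage 3
  expect_equal(detect_aki(series_df(c(0, 30, 60), c(100, 100, 320)))$stage, 3L)
  expect_equal(detect_aki(series_df(c(0, 30, 60), c(300, 300, 460)))$stage, 3L)
  expect_equal(detect_aki(series_df(c(0, 30, 60), c(100, 100, 210)))$stage, 2L)

  # triggers 10 days apart merge into one episode; >= gap stays two
  merged <- detect_aki(series_df(c(0, 30, 60, 70), c(100, 100, 160, 170)))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$peak_ratio, 1.7)
  two <- detect_aki(series_df(c(0, 30, 60, 180), c(100, 100, 160, 160)))
  expect_equal(nrow(two), 2)

  # criteria_enabled restriction: ratio rise invisible to criterion iii alone
  cfg3 <- aki_config(criteria_enabled = "iii")
  expect_equal(nrow(detect_aki(series_df(c(0, 30, 60), c(100, 100, 160)),
                               config = cfg3)), 0)
  expect_equal(nrow(detect_aki(series_df(c(0, 30), c(80, 80)))), 0)
})

test_that("detector is invariant to duplicated measurements and criteria
           i/ii are scale invariant", {
  cfg_ratio <- aki_config(criteria_enabled = c("i", "ii"))
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(4:12, 1)
    day <- sort(sample(0:730, m))
    scr <- 100 * exp(cumsum(rnorm(m, 0, 0.25)))
    s <- series_df(day, scr)
    base <- detect_aki(s)
    dup <- detect_aki(rbind(s, s[sample(m, 1), ]))
    expect_identical(base, dup)
    sc <- detect_aki(series_df(day, scr * 3.7), config = cfg_ratio)
    ref <- detect_aki(s, config = cfg_ratio)
    expect_equal(sc$onset_day, ref$onset_day)
    expect_equal(sc$trigger_criterion, ref$trigger_criterion)
    expect_equal(sc$peak_ratio, ref$peak_ratio, tolerance = 1e-12)
  }
})

test_that("classify_recurrence summarises episode lists", {
  expect_equal(classify_recurrence(NULL),
               list(aki_2yr = 0L, aki_recurrent = 0L,
                    aki_stage_max = NA_integer_))
  one <- data.frame(stage = 2L)
  expect_equal(classify_recurrence(one)$aki_2yr, 1L)
  expect_equal(classify_recurrence(one)$aki_recurrent, 0L)
  expect_equal(classify_recurrence(one)$aki_stage_max, 2L)
  two <- data.frame(stage = c(1L, 3L))
  expect_equal(classify_recurrence(two),
               list(aki_2yr = 1L, aki_recurrent = 1L, aki_stage_max = 3L))
})

test_that("adjudicate_outcome implements the sustained eGFR < 15 rule", {
  age <- 60; sex <- 1
  # healthy throughout -> censored at 5 years
  s <- egfr_series(seq(0, 2500, 100), rep(40, 26), age, sex)
  out <- adjudicate_outcome(s, landmark_day = 730, age_entry = age, sex = sex)
  expect_equal(out$event, "censored")
  expect_equal(out$time_years, 5)

  # drops below 15 at landmark+100, confirmed at +200... not yet 90 days ->
  # needs a confirmation >= 90 days after onset
  d <- c(0, 365, 730, 830, 930)
  s2 <- egfr_series(d, c(30, 30, 25, 12, 12), age, sex)
  out2 <- adjudicate_outcome(s2, landmark_day = 730, age_entry = age,
                             sex = sex)
  expect_equal(out2$event, "kidney_failure")
  expect_equal(out2$time_years, 100 / 365.25)

  # single dip back above threshold within 90 days -> not kidney failure
  s3 <- egfr_series(d, c(30, 30, 25, 12, 25), age, sex)
  expect_equal(adjudicate_outcome(s3, landmark_day = 730, age_entry = age,
                                  sex = sex)$event, "censored")

  # death during an unconfirmed low period -> death
  out4 <- adjudicate_outcome(s2[1:4, ], death_day = 1000, landmark_day = 730,
                             age_entry = age, sex = sex)
  expect_equal(out4$event, "death")
  expect_equal(out4$time_years, 270 / 365.25)

  # RRT dominates labs; kidney failure at the RRT day
  out5 <- adjudicate_outcome(s, rrt_day = 800, landmark_day = 730,
                             age_entry = age, sex = sex)
  expect_equal(out5$event, "kidney_failure")
  expect_equal(out5$time_years, 70 / 365.25)

  # beyond the horizon -> censored
  out6 <- adjudicate_outcome(s, rrt_day = 730 + 6 * 365.25,
                             landmark_day = 730, age_entry = age, sex = sex)
  expect_equal(out6$event, "censored")

  # pre-landmark death / rrt / sustained low signal exclusion
  expect_equal(adjudicate_outcome(s, death_day = 300, landmark_day = 730,
                                  age_entry = age, sex = sex)$event,
               "excluded")
  expect_equal(adjudicate_outcome(s, rrt_day = 300, landmark_day = 730,
                                  age_entry = age, sex = sex)$event,
               "excluded")
  slow <- egfr_series(c(0, 100, 200, 400, 800), c(20, 12, 12, 12, 12),
                      age, sex)
  expect_equal(adjudicate_outcome(slow, landmark_day = 730,
                                  age_entry = age, sex = sex)$reason,
               "sustained_low_before_landmark")
})

test_that("adjudicate_decline30 uses 70% of the landmark eGFR", {
  age <- 60; sex <- 0
  d <- c(0, 365, 730, 830, 930, 1030)
  # landmark eGFR 50 -> threshold 35; sustained 34 is an event
  ev <- adjudicate_decline30(egfr_series(d, c(55, 52, 50, 34, 34, 34), age,
                                         sex),
                             landmark_day = 730, age_entry = age, sex = sex)
  expect_equal(ev$event, "kidney_failure")
  expect_equal(ev$time_years, 100 / 365.25, tolerance = 1e-6)
  # 36 > 35: no event
  no <- adjudicate_decline30(egfr_series(d, c(55, 52, 50, 36, 36, 36), age,
                                         sex),
                             landmark_day = 730, age_entry = age, sex = sex)
  expect_equal(no$event, "censored")
  # RRT one year after the landmark
  rrt <- adjudicate_decline30(egfr_series(d, rep(50, 6), age, sex),
                              rrt_day = 730 + 365.25, landmark_day = 730,
                              age_entry = age, sex = sex)
  expect_equal(rrt$time_years, 1)
  # a deep pre-landmark AKI dip must not trigger the decline endpoint
  dipped <- egfr_series(c(0, 300, 400, 500, 730, 1000, 1200),
                        c(50, 20, 20, 20, 50, 45, 45), age, sex)
  expect_equal(adjudicate_decline30(dipped, landmark_day = 730,
                                    age_entry = age, sex = sex)$event,
               "censored")
})

test_that("build_landmark_cohort applies exclusions and codes covariates", {
  age <- 60
  mk_labs <- function(pid, egfr)
    data.frame(patient_id = pid, day = seq(0, 730, 146),
               scr_umol_l = creatinine_from_egfr(
                 egfr, age + seq(0, 730, 146) / 365.25, 1))
  patients <- data.frame(patient_id = 1:4, age_years = age, sex = 1,
                         acr_mg_g = c(400, 100, 10, NA),
                         diagnosis = "vascular_htn", diabetes = 0,
                         sbp = 140, dbp = 80)
  labs <- rbind(mk_labs(1, 50), mk_labs(2, 50), mk_labs(3, 50),
                mk_labs(4, 50))
  events <- data.frame(patient_id = 1:4,
                       rrt_day = c(NA, 800, NA, NA),
                       death_day = c(300, NA, NA, NA))
  rows <- build_landmark_cohort(patients, labs, events)
  expect_equal(nrow(rows), 3)                      # patient 1 died pre-landmark
  expect_equal(attr(rows, "exclusions")[["death_before_landmark"]], 1L)
  r2 <- rows[rows$patient_id == 2, ]
  expect_equal(r2$event, "kidney_failure")
  expect_equal(r2$time_years, (800 - 730) / 365.25)
  expect_equal(rows$proteinuria_cat[match(2:4, rows$patient_id)],
               c("moderate", "none_mild", "not_tested"))
  expect_equal(rows$age_landmark, rep(age + 730 / 365.25, 3))
  # zero labs -> excluded with count
  rows2 <- build_landmark_cohort(patients[3:4, ], labs[0, ], events[3:4, ])
  expect_equal(nrow(rows2), 0)
  expect_equal(attr(rows2, "exclusions")[["no_labs"]], 2L)
})

test_that("event labels partition every cohort", {
  rows <- rows_ge30_4k()
  expect_equal(sum(rows$event == "kidney_failure") +
                 sum(rows$event == "death") +
                 sum(rows$event == "censored"), nrow(rows))
  expect_true(all(rows$time_years > 0 & rows$time_years <= 5))
})
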