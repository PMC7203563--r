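# Cause-specific Cox and Fine-Gray contracts: parameter recovery, exact
# reductions, invariances, and the nonparametric estimators.

test_that("cause-specific Cox recovers a known hazard ratio and is null
           consistent", {
  rows <- two_group_exp(20000, hr = 2, seed = 21)
  fit <- fit_cox_cause_specific(rows, list(cov_term("x")), "kidney_failure")
  expect_equal(unname(fit$coefficients["x"]), log(2), tolerance = 0.05)
  # likelihood ascent over the null model
  expect_gte(fit$loglik[2], fit$loglik[1])
  # Wald CI covers the truth
  hr <- hazard_ratios(fit)
  expect_true(hr["x", "lo"] < 2 && 2 < hr["x", "hi"])

  null_rows <- two_group_exp(5000, hr = 1, seed = 22)
  nf <- fit_cox_cause_specific(null_rows, list(cov_term("x")),
                               "kidney_failure")
  expect_lt(abs(nf$coefficients["x"]), 2 * nf$se["x"])
})

test_that("design contracts: zero variance, missing events, separation", {
  rows <- two_group_exp(200, hr = 1, seed = 1)
  rows$z <- 1
  expect_error(fit_cox_cause_specific(rows, list(cov_term("z")),
                                      "kidney_failure"), "zero-variance")
  expect_error(fit_cox_cause_specific(rows, list(cov_term("x")), "death"),
               "no events")
})

test_that("coefficients are invariant to covariate shift and equivariant to
           scale", {
  rows <- two_group_exp(3000, hr = 1.8, seed = 31)
  rows$w <- rnorm(3000)
  spec <- list(cov_term("x"), cov_term("w"))
  f0 <- fit_cox_cause_specific(rows, spec, "kidney_failure")
  rows2 <- rows; rows2$w <- rows$w + 17
  f1 <- fit_cox_cause_specific(rows2, spec, "kidney_failure")
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-8)
  rows3 <- rows; rows3$w <- rows$w * 4
  f2 <- fit_cox_cause_specific(rows3, spec, "kidney_failure")
  expect_equal(unname(f2$coefficients["w"] * 4),
               unname(f0$coefficients["w"]), tolerance = 1e-8)
  expect_equal(unname(f2$coefficients["x"]), unname(f0$coefficients["x"]),
               tolerance = 1e-8)
})

test_that("Fine-Gray reduces exactly to Cox without competing events", {
  rows <- two_group_exp(4000, hr = 1.6, seed = 41)  # no deaths at all
  fg <- fit_fine_gray(rows, list(cov_term("x")), "kidney_failure")
  cx <- fit_cox_cause_specific(rows, list(cov_term("x")), "kidney_failure")
  expect_lt(abs(fg$coefficients["x"] - cx$coefficients["x"]), 1e-6)
})

test_that("under purely administrative censoring Fine-Gray equals an
           unweighted fit keeping competing events at risk", {
  set.seed(51)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n) / (0.15 * 1.7^x)
  t2 <- rexp(n) / 0.15
  t <- pmin(t1, t2, 5)
  ev <- ifelse(t == 5, "censored",
               ifelse(t1 <= t2, "kidney_failure", "death"))
  rows <- data.frame(x = x, event = ev, time_years = t)
  fg <- fit_fine_gray(rows, list(cov_term("x")), "kidney_failure")
  # oracle: competing-event subjects stay at risk (weight 1, G constant
  # before the administrative horizon) until 5 years
  stop2 <- ifelse(rows$event == "kidney_failure", rows$time_years, 5)
  oracle <- survival::coxph(
    survival::Surv(stop2, rows$event == "kidney_failure") ~ x,
    ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  expect_lt(abs(fg$coefficients["x"] - coef(oracle)[["x"]]), 1e-6)
})

test_that("Fine-Gray recovers the generating subdistribution coefficient", {
  # average over three fixed seeds so the check reflects the estimator, not
  # one Monte-Carlo draw (single-draw SE at n = 20000 is ~0.024)
  betas <- vapply(c(61, 62, 63), function(s) {
    rows <- sim_fine_gray(20000, beta = 0.5, seed = s)
    unname(fit_fine_gray(rows, list(cov_term("x")),
                         "kidney_failure")$coefficients["x"])
  }, numeric(1))
  expect_equal(mean(betas), 0.5, tolerance = 0.06 / 0.5)
})

test_that("Aalen-Johansen: reduction, conservation and the exponential
           closed form", {
  # single cause, no censoring: CIF is the empirical CDF
  set.seed(71)
  t <- rexp(300, 1)
  rows1 <- data.frame(event = "kidney_failure", time_years = t)
  cif <- aalen_johansen_cif(rows1, "kidney_failure")$all
  ecdf_at <- ecdf(t)(cif$time)
  expect_equal(cif$cif, ecdf_at, tolerance = 1e-10)

  # two causes: CIF_kf + CIF_death + KM = 1 at event times
  rows <- sim_fine_gray(2000, beta = 0.4, seed = 72)
  c_kf <- aalen_johansen_cif(rows, "kidney_failure")$all
  c_de <- aalen_johansen_cif(rows, "death")$all
  km <- survival::survfit(
    survival::Surv(rows$time_years, rows$event != "censored") ~ 1)
  s_at <- approx(c(0, km$time), c(1, km$surv), xout = c_kf$time,
                 method = "constant", rule = 2)$y
  d_at <- approx(c_de$time, c_de$cif, xout = c_kf$time,
                 method = "constant", rule = 2)$y
  expect_equal(c_kf$cif + d_at + s_at, rep(1, nrow(c_kf)), tolerance = 1e-8)

  # lambda1 = lambda2 = 0.2/yr: CIF_1(5) = 0.5 (1 - e^-2)
  set.seed(73)
  n <- 50000
  ta <- rexp(n, 0.2); tb <- rexp(n, 0.2)
  tm <- pmin(ta, tb, 5)
  rows2 <- data.frame(
    event = ifelse(tm == 5, "censored",
                   ifelse(ta <= tb, "kidney_failure", "death")),
    time_years = tm)
  cc <- aalen_johansen_cif(rows2, "kidney_failure")$all
  expect_equal(cc$cif[nrow(cc)], 0.5 * (1 - exp(-2)), tolerance = 0.01)

  expect_error(aalen_johansen_cif(rows2, "kidney_failure", group = "x"),
               "unknown grouping")
  rows2$g <- rep(c("a", "b"), n / 2)
  expect_error(aalen_johansen_cif(rows2, "kidney_failure", group = "g",
                                  labels = "zzz"), "unknown group label")
})

test_that("-ln(-ln S) curves are parallel under proportional hazards", {
  set.seed(81)
  n <- 8000
  g <- rep(0:1, each = n / 2)
  t <- rexp(n) / (0.3 * 2^g)
  rows <- data.frame(g = ifelse(g == 1, "exposed", "control"),
                     event = ifelse(t < 5, "kidney_failure", "censored"),
                     time_years = pmin(t, 5))
  curves <- loglog_survival(rows, "g")
  grid <- seq(0.5, 3, 0.25)
  off <- approx(curves$control$time, curves$control$loglog, grid)$y -
    approx(curves$exposed$time, curves$exposed$loglog, grid)$y
  expect_equal(mean(off), log(2), tolerance = 0.1)
  expect_lt(diff(range(off)), 0.2)

  # identical groups: offset ~ 0
  rows$g2 <- rep(c("a", "b"), n / 2)
  curves2 <- loglog_survival(rows, "g2")
  off2 <- approx(curves2$a$time, curves2$a$loglog, grid)$y -
    approx(curves2$b$time, curves2$b$loglog, grid)$y
  expect_lt(abs(mean(off2)), 0.1)

  # crossing hazards: offset changes sign
  tw <- c(rweibull(n / 2, 0.5, 2), rweibull(n / 2, 2, 2))
  rows3 <- data.frame(g = rep(c("early", "late"), each = n / 2),
                      event = ifelse(tw < 5, "kidney_failure", "censored"),
                      time_years = pmin(tw, 5))
  curves3 <- loglog_survival(rows3, "g")
  off3 <- approx(curves3$early$time, curves3$early$loglog, grid)$y -
    approx(curves3$late$time, curves3$late$loglog, grid)$y
  expect_true(min(off3, na.rm = TRUE) < 0 && max(off3, na.rm = TRUE) > 0)

  rows$event[rows$g == "control"] <- "censored"
  expect_warning(loglog_survival(rows, "g"), "no events")
})

test_that("predict_absolute_risk follows the 1 - S0^exp(LP) contract", {
  rows <- sim_fine_gray(4000, beta = 0.7, seed = 91)
  fg <- fit_fine_gray(rows, list(cov_term("x")), "kidney_failure")
  r0 <- predict_absolute_risk(fg, data.frame(x = 0))
  h0 <- renalrisk:::baseline_cumhaz_at(fg, 5)
  expect_equal(r0, 1 - exp(-h0))          # LP = 0 -> 1 - S0(5)
  r1 <- predict_absolute_risk(fg, data.frame(x = 1))
  expect_gt(r1, r0)                        # positive coefficient
  far <- predict_absolute_risk(fg, data.frame(x = -40))
  expect_lt(far, 1e-6)                     # LP -> -inf: risk -> 0
  expect_warning(predict_absolute_risk(fg, data.frame(x = 0),
                                       horizon_years = 50),
                 "beyond last event time")
})

test_that("the AKI coefficient attenuates when eGFR enters a confounded
           scenario", {
  cfg <- scenario_config(n_patients = 6000, seed = 101,
                         aki_rate_per_year = 0.12,
                         aki_link = c(diabetes = 0, lnacr = 0, egfr10 = 0.8))
  co <- generate_cohort(cfg)
  rows <- build_landmark_cohort(co$patients, co$labs, co$events)
  crude <- fit_cox_cause_specific(rows, spec_stepwise("none"),
                                  "kidney_failure")
  adj <- fit_cox_cause_specific(rows, spec_stepwise("age_sex_egfr"),
                                "kidney_failure")
  expect_gt(crude$coefficients["aki_2yr"], adj$coefficients["aki_2yr"])
})
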