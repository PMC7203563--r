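# Independent oracles and small fixture builders used across the suite.

# direct re-evaluation of the printed 5-year KFRE (kept deliberately in a
# different algebraic arrangement from the implementation)
kfre_oracle <- function(age, sex, egfr, acr) {
  coefs <- c(-0.2201, 0.2467, -0.5567, 0.451)
  terms <- c(age / 10 - 7.036, sex - 0.5642, egfr / 5 - 7.222,
             log(acr) - 5.137)
  1 - 0.924^exp(sum(coefs * terms))
}

# brute-force pairwise concordance (ties count 1/2)
auc_brute <- function(risk, outcome) {
  x <- risk[outcome == 1]; y <- risk[outcome == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

series_df <- function(day, scr) data.frame(day = day, scr = scr)

flat_series <- function(days, value = 100) series_df(days, rep(value, length(days)))

# series whose eGFR at each day hits the requested targets for a given
# patient (inverts CKD-EPI at the age reached on that day)
egfr_series <- function(day, egfr, age_entry, sex) {
  series_df(day, creatinine_from_egfr(egfr, age_entry + day / 365.25, sex))
}

# two-group exponential competing-risk-free rows with true hazard ratio `hr`
two_group_exp <- function(n, hr, seed = 1, censor = 5, base = 0.2) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n) / (base * hr^x)
  data.frame(x = x,
             event = ifelse(t < censor, "kidney_failure", "censored"),
             time_years = pmin(t, censor))
}

# simulation from a known Fine-Gray subdistribution model (Fine & Gray 1999
# construction): F1(t|x) = 1 - (1 - p(1 - e^-t))^exp(beta x)
sim_fine_gray <- function(n, beta, p = 0.3, seed = 1, censor = 5,
                          rate2 = 0.3) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  eta <- exp(beta * x)
  p1 <- 1 - (1 - p)^eta              # lifetime cause-1 incidence
  cause1 <- runif(n) < p1
  u <- runif(n)
  # invert F1(t|x)/F1(inf|x) for cause-1 subjects
  t1 <- -log(1 - (1 - (1 - u * p1)^(1 / eta)) / p)
  t2 <- rexp(n) / rate2
  t <- ifelse(cause1, t1, t2)
  ev <- ifelse(cause1, "kidney_failure", "death")
  data.frame(x = x,
             event = ifelse(t < censor, ev, "censored"),
             time_years = pmin(t, censor))
}
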