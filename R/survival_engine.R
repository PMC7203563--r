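# Cause-specific Cox and Fine-Gray subdistribution fits on landmark rows.
# Partial-likelihood machinery is delegated to the survival package (Efron
# ties; finegray() builds the IPCW-weighted subdistribution risk sets with a
# Kaplan-Meier censoring distribution); this module owns the covariate
# transform layer, the model contracts, and baseline-anchored prediction.

EVENT_LEVELS <- c("censored", "kidney_failure", "death")

#' Covariate term for a model specification
#'
#' @param var column name in the analysis rows
#' @param transform one of "identity", "shift_scale" ((x - center)/scale),
#'   "inv_square" ((30/x)^2 - center, proportional to x^-2; the default
#'   center 1 anchors eGFR = 30 at zero), "ln_shift" ((ln x - center)/scale),
#'   "categorical" (reference-cell dummies)
#' @param center,scale transform constants
#' @param ref reference level (categorical)
#' @param levels full level set (categorical); defaults to the sorted levels
#'   observed in the data with `ref` first
#' @param name label for the term (defaults to `var`)
#' @return list of class `cov_term`
#' @export
cov_term <- function(var,
                     transform = c("identity", "shift_scale", "inv_square",
                                   "ln_shift", "categorical"),
                     center = NULL, scale = 1, ref = NULL, levels = NULL,
                     name = var) {
  transform <- match.arg(transform)
  if (is.null(center))
    center <- if (transform == "inv_square") 1 else 0
  structure(list(var = var, transform = transform, center = center,
                 scale = scale, ref = ref, levels = levels, name = name),
            class = "cov_term")
}

# expand one term into a named column matrix
term_columns <- function(term, data) {
  x <- data[[term$var]]
  if (is.null(x)) stop("term '", term$name, "': column '", term$var,
                       "' not found")
  if (term$transform == "categorical") {
    x <- as.character(x)
    lev <- term$levels
    if (is.null(lev)) {
      lev <- sort(unique(x))
      if (!is.null(term$ref)) lev <- c(term$ref, setdiff(lev, term$ref))
    }
    ref <- if (is.null(term$ref)) lev[1] else term$ref
    bad <- setdiff(unique(x), lev)
    if (length(bad)) stop("term '", term$name, "': unknown level(s) ",
                          paste(bad, collapse = ", "))
    cols <- sapply(setdiff(lev, ref), function(l) as.numeric(x == l))
    cols <- matrix(cols, nrow = length(x),
                   dimnames = list(NULL, paste0(term$name, "_",
                                                setdiff(lev, ref))))
    return(cols)
  }
  v <- switch(term$transform,
    identity = x,
    shift_scale = (x - term$center) / term$scale,
    inv_square = (30 / x)^2 - term$center,
    ln_shift = (log(x) - term$center) / term$scale
  )
  matrix(v, ncol = 1, dimnames = list(NULL, term$name))
}

#' Build a design matrix from a covariate specification
#'
#' @param data analysis rows
#' @param spec list of [cov_term()]s
#' @return numeric matrix; the all-zero row is the reference profile
#' @export
build_design <- function(data, spec) {
  stopifnot(length(spec) >= 1)
  X <- do.call(cbind, lapply(spec, term_columns, data = data))
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  X
}

#' Covariate ladders for the stepwise cause-specific models
#'
#' Reproduces the published adjustment ladder: AKI exposure alone, then
#' age (linear, centered at 70 per decade) and sex, then eGFR as an
#' inverse-square term, then the four KDIGO albuminuria categories, then
#' primary renal diagnosis.
#'
#' @param adjust one of "none", "age_sex", "age_sex_egfr",
#'   "age_sex_egfr_prot", "full"
#' @param exposure exposure column, default `aki_2yr` (use `aki_recurrent`
#'   for the recurrent-episode comparison)
#' @return list of [cov_term()]s
#' @export
spec_stepwise <- function(adjust = c("full", "none", "age_sex",
                                     "age_sex_egfr", "age_sex_egfr_prot"),
                          exposure = "aki_2yr") {
  adjust <- match.arg(adjust)
  terms <- list(cov_term(exposure))
  if (adjust == "none") return(terms)
  terms <- c(terms, list(
    cov_term("age_landmark", "shift_scale", center = 70, scale = 10,
             name = "age10"),
    cov_term("sex")))
  if (adjust == "age_sex") return(terms)
  terms <- c(terms, list(cov_term("egfr_landmark", "inv_square",
                                  name = "egfr_inv2")))
  if (adjust == "age_sex_egfr") return(terms)
  terms <- c(terms, list(cov_term(
    "proteinuria_cat", "categorical", ref = "none_mild",
    levels = c("none_mild", "moderate", "severe", "not_tested"),
    name = "prot")))
  if (adjust == "age_sex_egfr_prot") return(terms)
  c(terms, list(cov_term("diagnosis_cat", "categorical",
                         ref = "vascular_htn", levels = DIAG_LEVELS,
                         name = "diag")))
}

#' Covariate specification of the refitted KFRE-style models
#'
#' Age (per decade, centered at 70), eGFR per 5 units centered at 30, sex,
#' continuous lnACR, and optionally the 2-year AKI flag; the all-zero
#' profile is age 70, female, eGFR 30, ACR 1 mg/g, no AKI.
#'
#' @param include_aki add the AKI exposure flag
#' @return list of [cov_term()]s
#' @export
spec_refit <- function(include_aki = FALSE) {
  terms <- list(
    cov_term("age_landmark", "shift_scale", center = 70, scale = 10,
             name = "age10"),
    cov_term("egfr_landmark", "shift_scale", center = 30, scale = 5,
             name = "egfr5"),
    cov_term("sex"),
    cov_term("lnacr"))
  if (include_aki) terms <- c(terms, list(cov_term("aki_2yr")))
  terms
}

check_rows <- function(rows) {
  stopifnot(all(c("event", "time_years") %in% names(rows)))
  if (!all(rows$event %in% EVENT_LEVELS))
    stop("event must be one of ", paste(EVENT_LEVELS, collapse = ", "))
  if (any(rows$time_years <= 0)) stop("event times must be positive")
  rows
}

new_renal_fit <- function(cox, X, spec, model_kind, cause) {
  beta <- coef(cox)
  if (any(abs(beta) > 50))
    stop("monotone partial likelihood (perfect separation?): |coef| > 50 ",
         "for ", paste(names(beta)[abs(beta) > 50], collapse = ", "))
  bh <- survival::basehaz(cox, centered = FALSE)
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vcov(cox))),
    vcov = vcov(cox),
    loglik = cox$loglik,
    n = cox$n, n_events = cox$nevent,
    basehaz = data.frame(time = bh$time, cumhaz = bh$hazard),
    model_kind = model_kind, cause = cause, spec = spec
  ), class = "renal_fit")
}

#' @export
print.renal_fit <- function(x, ...) {
  cat(sprintf("%s fit for cause '%s' (%d rows, %d events)\n",
              x$model_kind, x$cause, x$n, x$n_events))
  ci <- hazard_ratios(x)
  print(round(ci, 4))
  invisible(x)
}

#' Hazard ratios with Wald 95% confidence intervals
#'
#' @param fit a fit from [fit_cox_cause_specific()] or [fit_fine_gray()]
#' @return data.frame with hr, lo, hi, coef, se per term
#' @export
hazard_ratios <- function(fit) {
  b <- fit$coefficients; s <- fit$se
  data.frame(hr = exp(b), lo = exp(b - 1.96 * s), hi = exp(b + 1.96 * s),
             coef = b, se = s, row.names = names(b))
}

validate_design <- function(X, spec) {
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance term(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  X
}

#' Cause-specific Cox proportional hazards fit
#'
#' Maximizes the Efron-tie-corrected partial likelihood for the given cause,
#' treating other-cause events as censored at their event time. Convergence
#' control: `coxph.control(eps = 1e-9, iter.max = 100)`.
#'
#' @param rows landmark rows with `event` and `time_years`
#' @param spec list of [cov_term()]s
#' @param cause "kidney_failure" or "death"
#' @return object of class `renal_fit`
#' @export
fit_cox_cause_specific <- function(rows, spec,
                                   cause = c("kidney_failure", "death")) {
  cause <- match.arg(cause)
  rows <- check_rows(rows)
  X <- validate_design(build_design(rows, spec), spec)
  status <- as.integer(rows$event == cause)
  if (sum(status) < 1) stop("no events of cause '", cause, "'")
  df <- data.frame(.time = rows$time_years, .status = status, X,
                   check.names = FALSE)
  f <- stats::as.formula(paste(
    "Surv(.time, .status) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  cox <- coxph(f, data = df, ties = "efron",
               control = coxph.control(eps = 1e-9, iter.max = 100))
  names(cox$coefficients) <- colnames(X)
  fit <- new_renal_fit(cox, X, spec, "cause_specific_cox", cause)
  fit
}

#' Fine-Gray subdistribution hazard fit
#'
#' Subjects failing from the competing cause remain in later risk sets with
#' inverse-probability-of-censoring weights G(t)/G(min(T_i, t)), where G is
#' the overall Kaplan-Meier estimator of the censoring distribution
#' (`survival::finegray()`); the weighted Efron partial likelihood is then
#' maximized as in [fit_cox_cause_specific()]. The baseline cumulative
#' subdistribution hazard is anchored at the all-zero (reference) profile of
#' `spec`.
#'
#' @inheritParams fit_cox_cause_specific
#' @return object of class `renal_fit`
#' @export
fit_fine_gray <- function(rows, spec,
                          cause = c("kidney_failure", "death")) {
  cause <- match.arg(cause)
  rows <- check_rows(rows)
  X <- validate_design(build_design(rows, spec), spec)
  if (sum(rows$event == cause) < 1) stop("no events of cause '", cause, "'")
  ev <- factor(rows$event, levels = EVENT_LEVELS)
  dat <- data.frame(.time = rows$time_years, .ev = ev, X,
                    check.names = FALSE)
  fg <- survival::finegray(Surv(.time, .ev) ~ ., data = dat, etype = cause)
  if (anyNA(fg$fgwt) || any(fg$fgwt < 0))
    stop("censoring survival G(t) reached 0 inside the needed region; ",
         "truncate follow-up before fitting")
  f <- stats::as.formula(paste(
    "Surv(fgstart, fgstop, fgstatus) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  cox <- coxph(f, data = fg, weights = fg$fgwt, ties = "efron",
               control = coxph.control(eps = 1e-9, iter.max = 100))
  names(cox$coefficients) <- colnames(X)
  new_renal_fit(cox, X, spec, "fine_gray", cause)
}

baseline_cumhaz_at <- function(fit, horizon) {
  bh <- fit$basehaz
  if (horizon > max(bh$time)) {
    warning("horizon ", horizon, " beyond last event time ",
            round(max(bh$time), 4), "; using the last baseline value")
    return(bh$cumhaz[nrow(bh)])
  }
  idx <- findInterval(horizon, bh$time)
  if (idx == 0) 0 else bh$cumhaz[idx]
}

#' Absolute risk at a horizon from a Fine-Gray fit
#'
#' risk = 1 - S0(horizon)^exp(LP), with S0 = exp(-baseline cumulative
#' subdistribution hazard) evaluated at the reference (all-zero) profile.
#'
#' @param fit a `renal_fit` of kind "fine_gray"
#' @param newdata rows providing the spec's covariates
#' @param horizon_years prediction horizon
#' @return numeric vector of risks in [0, 1]
#' @export
predict_absolute_risk <- function(fit, newdata, horizon_years = 5) {
  stopifnot(inherits(fit, "renal_fit"))
  X <- build_design(newdata, fit$spec)
  lp <- drop(X %*% fit$coefficients)
  H0 <- baseline_cumhaz_at(fit, horizon_years)
  1 - exp(-H0 * exp(lp))
}

#' Linear predictor under a fitted model
#' @inheritParams predict_absolute_risk
#' @export
linear_predictor <- function(fit, newdata) {
  drop(build_design(newdata, fit$spec) %*% fit$coefficients)
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric cumulative incidence of `cause` accounting for competing
#' events, optionally stratified by a grouping column.
#'
#' @param rows landmark rows
#' @param cause "kidney_failure" or "death"
#' @param group optional name of a grouping column in `rows`
#' @param labels optional subset of group labels to return; unknown labels
#'   are an error
#' @return named list of data.frames (time, cif), one per group ("all" when
#'   ungrouped)
#' @export
aalen_johansen_cif <- function(rows, cause = c("kidney_failure", "death"),
                               group = NULL, labels = NULL) {
  cause <- match.arg(cause)
  rows <- check_rows(rows)
  ev <- factor(rows$event, levels = EVENT_LEVELS)
  if (is.null(group)) {
    g <- factor(rep("all", nrow(rows)))
  } else {
    if (!group %in% names(rows)) stop("unknown grouping column: ", group)
    g <- factor(rows[[group]])
  }
  if (!is.null(labels)) {
    bad <- setdiff(labels, levels(g))
    if (length(bad)) stop("unknown group label(s): ",
                          paste(bad, collapse = ", "))
  } else labels <- levels(g)
  out <- list()
  for (l in labels) {
    sel <- g == l
    if (!any(sel)) stop("empty group: ", l)
    sf <- survfit(Surv(time_years, ev) ~ 1, data = rows[sel, , drop = FALSE])
    col <- match(cause, sf$states)
    out[[l]] <- data.frame(time = c(0, sf$time),
                           cif = c(0, sf$pstate[, col]))
  }
  out
}

#' Complementary log-log survival curves per group
#'
#' Kaplan-Meier survival per group transformed to -ln(-ln S(t)); under
#' proportional hazards the curves are vertically parallel with offset equal
#' to the log hazard ratio. Groups without events are omitted with a
#' warning.
#'
#' @param rows landmark rows (any event counts as the event)
#' @param group name of the grouping column
#' @return named list of data.frames (time, loglog)
#' @export
loglog_survival <- function(rows, group) {
  rows <- check_rows(rows)
  if (!group %in% names(rows)) stop("unknown grouping column: ", group)
  g <- factor(rows[[group]])
  out <- list()
  for (l in levels(g)) {
    sel <- g == l
    status <- as.integer(rows$event[sel] != "censored")
    if (sum(status) == 0) {
      warning("group '", l, "' has no events; curve omitted")
      next
    }
    sf <- survfit(Surv(rows$time_years[sel], status) ~ 1)
    keep <- sf$n.event > 0 & sf$surv > 0 & sf$surv < 1
    out[[l]] <- data.frame(time = sf$time[keep],
                           loglog = -log(-log(sf$surv[keep])))
  }
  out
}
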