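# 5-year absolute kidney failure risk models of the form
# risk = 1 - S0^exp(LP): the published 4-variable / 5-year KFRE evaluated
# exactly as printed, and refitted Fine-Gray models (with/without the AKI
# flag) whose baseline subdistribution survival is anchored at the reference
# profile (age 70, female, eGFR 30, ACR 1 mg/g, no AKI).

#' Published 5-year KFRE (4-variable)
#'
#' Exact evaluation of the published equation
#' `1 - 0.924^exp(-0.2201*(age/10 - 7.036) + 0.2467*(sex - 0.5642)
#'   - 0.5567*(eGFR/5 - 7.222) + 0.451*(lnACR - 5.137))`
#' with sex = 1 male / 0 female and lnACR the natural log of the
#' albumin:creatinine ratio in mg/g.
#'
#' @param age age in years
#' @param sex 1 male / 0 female
#' @param egfr eGFR, mL/min/1.73 m^2
#' @param acr albumin:creatinine ratio, mg/g (> 0; resolve missing ACR
#'   upstream)
#' @return 5-year kidney failure risk in (0, 1)
#' @export
kfre_5yr <- function(age, sex, egfr, acr) {
  if (any(is.na(acr)) || any(acr <= 0))
    stop("kfre_5yr: acr must be positive (missing ACR must be resolved upstream)")
  lp <- -0.2201 * (age / 10 - 7.036) + 0.2467 * (sex - 0.5642) -
    0.5567 * (egfr / 5 - 7.222) + 0.451 * (log(acr) - 5.137)
  1 - 0.924^exp(lp)
}

new_risk_model <- function(name, s0, spec, coefficients, fit = NULL) {
  stopifnot(s0 > 0, s0 < 1, length(coefficients) >= 1)
  structure(list(name = name, s0 = s0, spec = spec,
                 coefficients = coefficients, fit = fit),
            class = "risk_model")
}

#' The published 5-year KFRE as a `risk_model` object
#'
#' Same model as [kfre_5yr()], expressed over landmark cohort rows
#' (columns `age_landmark`, `sex`, `egfr_landmark`, `lnacr`).
#'
#' @return object of class `risk_model`
#' @export
kfre_model <- function() {
  spec <- list(
    cov_term("age_landmark", "shift_scale", center = 70.36, scale = 10,
             name = "age10"),
    cov_term("sex", "shift_scale", center = 0.5642, scale = 1,
             name = "sex"),
    cov_term("egfr_landmark", "shift_scale", center = 36.11, scale = 5,
             name = "egfr5"),
    cov_term("lnacr", "shift_scale", center = 5.137, scale = 1,
             name = "lnacr"))
  new_risk_model("kfre_5yr", 0.924, spec,
                 c(age10 = -0.2201, sex = 0.2467, egfr5 = -0.5567,
                   lnacr = 0.451))
}

#' Predict 5-year risk and linear predictor from a `risk_model`
#'
#' @param object a `risk_model`
#' @param newdata rows providing the model's covariates
#' @param ... unused
#' @return data.frame(risk, lp)
#' @export
predict.risk_model <- function(object, newdata, ...) {
  X <- build_design(newdata, object$spec)
  lp <- drop(X %*% object$coefficients)
  data.frame(risk = 1 - object$s0^exp(lp), lp = lp)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(x$name, ":", format_equation(x), "\n")
  invisible(x)
}

#' Refit a 5-year kidney failure risk model on landmark rows
#'
#' Fits a Fine-Gray subdistribution model for kidney failure (death
#' competing) on age (per decade, centered 70), eGFR (per 5, centered 30),
#' sex and continuous lnACR, optionally adding the 2-year AKI flag. Rows are
#' restricted to eGFR >= 30 and non-missing ACR (complete-case; see the
#' missing-ACR policy in the methods vignette). The baseline subdistribution
#' survival at 5 years, evaluated at the reference profile, becomes S0.
#'
#' @param rows landmark cohort rows
#' @param include_aki add `aki_2yr` as a predictor
#' @param horizon_years horizon at which S0 is anchored (default 5)
#' @param name model label
#' @return object of class `risk_model` (with the underlying `renal_fit` in
#'   `$fit`)
#' @export
refit_model <- function(rows, include_aki = FALSE, horizon_years = 5,
                        name = if (include_aki) "refit_with_aki"
                               else "refit_without_aki") {
  rows <- rows[rows$egfr_landmark >= 30, , drop = FALSE]
  if (all(is.na(rows$lnacr)))
    stop("all ACR missing: resolve the missing-ACR policy before refitting")
  rows <- rows[!is.na(rows$lnacr), , drop = FALSE]
  fit <- fit_fine_gray(rows, spec_refit(include_aki), "kidney_failure")
  s0 <- exp(-baseline_cumhaz_at(fit, horizon_years))
  new_risk_model(name, s0, fit$spec, fit$coefficients, fit = fit)
}

#' Algebraic form of a risk model
#'
#' Renders `1 - S0^exp(...)` with each centered term spelled out, mirroring
#' the published table layout.
#'
#' @param model a `risk_model`
#' @param digits significant digits for printing
#' @return character scalar
#' @export
format_equation <- function(model, digits = 4) {
  fmt <- function(v) formatC(signif(v, digits), format = "g")
  parts <- mapply(function(term, b) {
    inner <- switch(term$transform,
      identity = term$var,
      shift_scale = if (term$scale == 1)
        sprintf("(%s - %s)", term$var, fmt(term$center))
      else sprintf("((%s - %s)/%s)", term$var, fmt(term$center),
                   fmt(term$scale)),
      inv_square = sprintf("((30/%s)^2 - %s)", term$var, fmt(term$center)),
      ln_shift = sprintf("(ln(%s) - %s)", term$var, fmt(term$center)),
      categorical = term$var)
    sprintf("(%s * %s)", fmt(b), inner)
  }, model$spec[seq_along(model$coefficients)], model$coefficients)
  sprintf("1 - %s^exp(%s)", fmt(model$s0), paste(parts, collapse = " + "))
}

#' Serialize / restore a risk model (JSON)
#'
#' Full-precision round trip: a restored model reproduces identical
#' predictions.
#'
#' @param model a `risk_model`
#' @param path optional file; when `NULL` the JSON string is returned
#' @return `risk_model_to_json`: JSON string or (invisibly) `path`;
#'   `risk_model_from_json`: a `risk_model`
#' @export
risk_model_to_json <- function(model, path = NULL) {
  payload <- list(
    name = model$name, s0 = model$s0,
    coefficients = as.list(model$coefficients),
    terms = lapply(model$spec, function(t)
      t[c("var", "transform", "center", "scale", "ref", "levels", "name")])
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname risk_model_to_json
#' @param json JSON string or path to a JSON file
#' @export
risk_model_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  spec <- lapply(seq_len(nrow(p$terms)), function(i) {
    t <- p$terms[i, ]
    cov_term(t$var, t$transform, center = t$center, scale = t$scale,
             ref = if (is.null(t$ref) || is.na(t$ref)) NULL else t$ref,
             levels = if (is.null(t$levels[[1]])) NULL else t$levels[[1]],
             name = t$name)
  })
  new_risk_model(p$name, p$s0, spec, unlist(p$coefficients))
}

#' Predictions for several risk models over a cohort
#'
#' One prediction per (row, model). Rows outside a model's domain (missing
#' or nonpositive ACR, missing covariates) are excluded for that model and
#' counted in the `excluded` attribute.
#'
#' @param models named list of `risk_model`s
#' @param rows landmark cohort rows
#' @return data.frame(patient_id, model, risk, lp) with attribute `excluded`
#' @export
evaluate_models <- function(models, rows) {
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, `[[`, character(1), "name")
  out <- list(); excl <- integer(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    vars <- vapply(m$spec, `[[`, character(1), "var")
    ok <- rep(TRUE, nrow(rows))
    for (v in vars) ok <- ok & !is.na(rows[[v]])
    excl[nm] <- sum(!ok)
    if (!any(ok)) next
    pr <- predict(m, rows[ok, , drop = FALSE])
    out[[nm]] <- data.frame(patient_id = rows$patient_id[ok], model = nm,
                            risk = pr$risk, lp = pr$lp)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = integer(), model = character(),
               risk = numeric(), lp = numeric())
  rownames(res) <- NULL
  attr(res, "excluded") <- excl
  res
}
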