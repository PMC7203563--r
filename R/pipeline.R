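# Orchestration: generate -> detect/landmark -> fit -> validate -> report,
# reading and writing CSV artifacts so any downstream stage can be rerun
# from cached files. All randomness flows from the single config seed.

AGE_BAND_BREAKS <- c(-Inf, 60, 80, Inf)
AGE_BAND_LABELS <- c("lt60", "60_79", "ge80")
EGFR_BAND_BREAKS <- c(-Inf, 30, 45, 60, Inf)
EGFR_BAND_LABELS <- c("lt30", "30_44", "45_59", "ge60")

# tiny polynomial string hash (hex) so runs can stamp their config without
# external digest dependencies; arithmetic stays inside exact-double range
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

required_config_keys <- c("n_patients", "seed")

#' Read and validate a pipeline configuration (JSON)
#'
#' Minimal schema: `n_patients` and `seed` are required; optional keys are
#' `preset` ("default", "ge30", "lt30", "recurrent"), any scalar
#' [scenario_config()] field override, `aki_criteria` ("all", "i", "ii",
#' "iii"), `endpoint` ("kf15", "decline30"), and `make_plots`.
#'
#' @param path JSON file path, or a list already in memory
#' @return validated config list
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::fromJSON(path) else path
  missing_keys <- setdiff(required_config_keys, names(cfg))
  if (length(missing_keys))
    stop("config schema error; missing key(s): ",
         paste(missing_keys, collapse = ", "))
  cfg$preset <- if (is.null(cfg$preset)) "default" else cfg$preset
  cfg$aki_criteria <- if (is.null(cfg$aki_criteria)) "all" else cfg$aki_criteria
  cfg$endpoint <- if (is.null(cfg$endpoint)) "kf15" else cfg$endpoint
  cfg$make_plots <- isTRUE(cfg$make_plots)
  cfg
}

scenario_from_config <- function(cfg, seed = NULL) {
  maker <- switch(cfg$preset,
                  default = scenario_config,
                  ge30 = scenario_ge30,
                  lt30 = scenario_lt30,
                  recurrent = scenario_recurrent,
                  stop("unknown preset: ", cfg$preset))
  pass <- intersect(names(cfg), setdiff(names(formals(scenario_config)),
                                        c("effects", "aki_link")))
  args <- cfg[pass]
  if (!is.null(seed)) args$seed <- seed
  do.call(maker, args)
}

detector_config_from <- function(cfg) {
  if (identical(cfg$aki_criteria, "all")) aki_config()
  else aki_config(criteria_enabled = cfg$aki_criteria)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[renalrisk] %-9s %6.1fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

# --- report tables -------------------------------------------------------

characteristics_table <- function(rows) {
  add <- function(variable, level, sel) {
    data.frame(variable = variable, level = level,
               n_aki = sum(sel & rows$aki_2yr == 1),
               pct_aki = round(100 * sum(sel & rows$aki_2yr == 1) /
                                 max(sum(rows$aki_2yr == 1), 1), 1),
               n_no_aki = sum(sel & rows$aki_2yr == 0),
               pct_no_aki = round(100 * sum(sel & rows$aki_2yr == 0) /
                                    max(sum(rows$aki_2yr == 0), 1), 1))
  }
  out <- list(add("n", "total", rep(TRUE, nrow(rows))))
  ageb <- cut(rows$age_landmark, AGE_BAND_BREAKS, AGE_BAND_LABELS,
              right = FALSE)
  for (l in levels(ageb)) out <- c(out, list(add("age_band", l, ageb == l)))
  for (s in c(1, 0)) out <- c(out, list(
    add("sex", ifelse(s == 1, "male", "female"), rows$sex == s)))
  egfrb <- cut(rows$egfr_landmark, EGFR_BAND_BREAKS, EGFR_BAND_LABELS,
               right = FALSE)
  for (l in levels(egfrb)) out <- c(out, list(add("egfr_band", l, egfrb == l)))
  for (l in c("severe", "moderate", "none_mild", "not_tested"))
    out <- c(out, list(add("proteinuria", l, rows$proteinuria_cat == l)))
  for (l in unique(rows$diagnosis_cat))
    out <- c(out, list(add("diagnosis", l, rows$diagnosis_cat == l)))
  out <- c(out, list(add("diabetes", "yes", rows$diabetes == 1)))
  do.call(rbind, out)
}

outcomes_table <- function(rows) {
  strata <- list(overall = rep(TRUE, nrow(rows)))
  egfrb <- cut(rows$egfr_landmark, EGFR_BAND_BREAKS, EGFR_BAND_LABELS,
               right = FALSE)
  for (l in levels(egfrb)) strata[[paste0("egfr_", l)]] <- egfrb == l
  out <- list()
  for (nm in names(strata)) {
    for (a in c(1, 0)) {
      sel <- strata[[nm]] & rows$aki_2yr == a
      n <- sum(sel)
      out[[length(out) + 1]] <- data.frame(
        stratum = nm, aki = a, n = n,
        pct_kidney_failure = round(100 * sum(sel & rows$event ==
                                               "kidney_failure") / max(n, 1), 1),
        pct_death = round(100 * sum(sel & rows$event == "death") / max(n, 1), 1),
        pct_alive = round(100 * sum(sel & rows$event == "censored") /
                            max(n, 1), 1))
    }
  }
  do.call(rbind, out)
}

LADDER <- c("none", "age_sex", "age_sex_egfr", "age_sex_egfr_prot", "full")

stepwise_hr_table <- function(rows, exposure = "aki_2yr") {
  out <- list()
  for (stratum in c("lt30", "ge30")) {
    sel <- if (stratum == "lt30") rows$egfr_landmark < 30
           else rows$egfr_landmark >= 30
    sub <- rows[sel, , drop = FALSE]
    if (!nrow(sub) || !any(sub[[exposure]] == 1)) next
    for (adj in LADDER) {
      for (cause in c("kidney_failure", "death")) {
        # sparse strata in small runs can separate or fail to converge;
        # such rows are simply omitted from the report table
        fit <- suppressWarnings(
          try(fit_cox_cause_specific(sub, spec_stepwise(adj, exposure),
                                     cause), silent = TRUE))
        if (inherits(fit, "try-error")) next
        if (any(abs(fit$coefficients) > 25)) next
        hr <- hazard_ratios(fit)[exposure, ]
        out[[length(out) + 1]] <- data.frame(
          stratum = stratum, adjusted = adj, cause = cause,
          exposure = exposure, hr = hr$hr, lo = hr$lo, hi = hr$hi,
          coef = hr$coef, se = hr$se, n = fit$n, n_events = fit$n_events)
      }
    }
  }
  do.call(rbind, out)
}

model_comparison <- function(rows) {
  sub <- rows[rows$egfr_landmark >= 30 & !is.na(rows$lnacr), , drop = FALSE]
  models <- list(
    kfre_5yr = kfre_model(),
    refit_without_aki = refit_model(sub, include_aki = FALSE),
    refit_with_aki = refit_model(sub, include_aki = TRUE))
  preds <- lapply(models, function(m) predict(m, sub))
  pairs <- lapply(preds, function(p) outcome_pairs(sub, p$risk))
  aucs <- vapply(pairs, auc, numeric(1))
  cmp_kfre <- compare_auc(pairs$kfre_5yr, pairs$refit_without_aki)
  cmp_aki <- compare_auc(pairs$refit_without_aki, pairs$refit_with_aki)
  cals <- mapply(function(p, pr) calibration(p, pr$lp, sub),
                 pairs, preds, SIMPLIFY = FALSE)
  table4 <- data.frame(
    model = names(models),
    equation = vapply(models, format_equation, character(1)),
    s0 = vapply(models, `[[`, numeric(1), "s0"),
    calibration_slope = vapply(cals, `[[`, numeric(1), "slope"),
    slope_lo = vapply(cals, function(cl) cl$slope_ci[1], numeric(1)),
    slope_hi = vapply(cals, function(cl) cl$slope_ci[2], numeric(1)),
    auc = aucs,
    p_vs_next = c(cmp_kfre$p_value, cmp_aki$p_value, NA))
  dca <- decision_curve(lapply(preds, `[[`, "risk"),
                        pairs$refit_without_aki)
  bins <- do.call(rbind, lapply(names(cals), function(nm)
    cbind(model = nm, cals[[nm]]$bins)))
  list(table4 = table4, decision_curve = dca, calibration_bins = bins,
       models = models, n = nrow(sub))
}

# --- pipeline ------------------------------------------------------------

#' Run the full synthetic analysis pipeline
#'
#' generate -> detect/landmark -> fit -> validate -> report. Emits
#' `patients.csv` / `labs.csv` / `events.csv`, `landmark_cohort.csv`,
#' `table1_characteristics.csv`, `table2_outcomes.csv`,
#' `table3_stepwise_hr.csv`, `table4_models.csv`, `calibration_bins.csv`,
#' `decision_curve.csv` and `metrics.json` under `out_dir`. Rerunning with
#' the same config and seed reproduces identical outputs.
#'
#' @param config path to a JSON config, or a config list
#'   (see [read_pipeline_config()])
#' @param out_dir output directory
#' @param seed optional override of the config seed
#' @param stages subset of c("generate","landmark","fit","validate","report");
#'   later stages read earlier stages' artifacts from `out_dir`
#' @return list of class `pipeline_run`: config, seed, artifact paths,
#'   landmark rows, tables and metrics
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         stages = c("generate", "landmark", "fit",
                                    "validate", "report")) {
  t0 <- proc.time()[3]
  cfg <- read_pipeline_config(config)
  if (is.null(seed)) seed <- cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  rows <- NULL; tables <- list(); metrics <- list()

  if ("generate" %in% stages) {
    scen <- scenario_from_config(cfg, seed)
    cohort <- generate_cohort(scen)
    paths$cohort <- write_cohort(cohort, out_dir)
    stage_msg("generate", t0)
  }
  if ("landmark" %in% stages) {
    patients <- read.csv(file.path(out_dir, "patients.csv"))
    labs <- read.csv(file.path(out_dir, "labs.csv"))
    events <- read.csv(file.path(out_dir, "events.csv"))
    rows <- build_landmark_cohort(patients, labs, events,
                                  config = detector_config_from(cfg),
                                  endpoint = cfg$endpoint)
    paths$landmark <- file.path(out_dir, "landmark_cohort.csv")
    write.csv(rows, paths$landmark, row.names = FALSE)
    metrics$exclusions <- as.list(attr(rows, "exclusions"))
    stage_msg("landmark", t0)
  }
  if (is.null(rows) && any(c("fit", "validate", "report") %in% stages))
    rows <- read.csv(file.path(out_dir, "landmark_cohort.csv"))

  if ("fit" %in% stages) {
    tables$table1 <- characteristics_table(rows)
    tables$table2 <- outcomes_table(rows)
    tables$table3 <- stepwise_hr_table(rows)
    write.csv(tables$table1,
              file.path(out_dir, "table1_characteristics.csv"),
              row.names = FALSE)
    write.csv(tables$table2, file.path(out_dir, "table2_outcomes.csv"),
              row.names = FALSE)
    write.csv(tables$table3, file.path(out_dir, "table3_stepwise_hr.csv"),
              row.names = FALSE)
    stage_msg("fit", t0)
  }
  if ("validate" %in% stages) {
    cmpres <- model_comparison(rows)
    tables$table4 <- cmpres$table4
    write.csv(cmpres$table4, file.path(out_dir, "table4_models.csv"),
              row.names = FALSE)
    write.csv(cmpres$calibration_bins,
              file.path(out_dir, "calibration_bins.csv"), row.names = FALSE)
    write.csv(cmpres$decision_curve,
              file.path(out_dir, "decision_curve.csv"), row.names = FALSE)
    for (nm in names(cmpres$models))
      risk_model_to_json(cmpres$models[[nm]],
                         file.path(out_dir, paste0("model_", nm, ".json")))
    metrics$auc <- as.list(setNames(cmpres$table4$auc, cmpres$table4$model))
    metrics$calibration_slope <- as.list(
      setNames(cmpres$table4$calibration_slope, cmpres$table4$model))
    metrics$auc_p_kfre_vs_refit <- cmpres$table4$p_vs_next[1]
    metrics$auc_p_refit_vs_aki <- cmpres$table4$p_vs_next[2]
    if (cfg$make_plots) plot_validation(cmpres, out_dir)
    stage_msg("validate", t0)
  }
  if ("report" %in% stages) {
    metrics$n_landmark <- nrow(rows)
    metrics$n_aki <- sum(rows$aki_2yr == 1)
    metrics$event_counts <- as.list(table(rows$event))
    metrics$config_hash <- config_hash(cfg[order(names(cfg))])
    metrics$seed <- seed
    paths$metrics <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stage_msg("report", t0)
  }
  structure(list(config = cfg, seed = seed, paths = paths, rows = rows,
                 tables = tables, metrics = metrics, out_dir = out_dir),
            class = "pipeline_run")
}

plot_validation <- function(cmpres, out_dir) {
  grDevices::png(file.path(out_dir, "fig_calibration.png"), 700, 700)
  b <- cmpres$calibration_bins
  graphics::plot(b$mean_predicted, b$observed_proportion,
       col = as.integer(factor(b$model)), pch = 19,
       xlab = "Mean predicted 5-year risk", ylab = "Observed proportion")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = levels(factor(b$model)),
                   col = seq_along(levels(factor(b$model))), pch = 19)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "fig_decision_curve.png"), 700, 700)
  d <- cmpres$decision_curve
  graphics::plot(NULL, xlim = range(d$threshold), ylim = range(d$net_benefit),
       xlab = "Threshold probability", ylab = "Net benefit")
  for (i in seq_along(unique(d$model))) {
    nm <- unique(d$model)[i]
    graphics::lines(d$threshold[d$model == nm], d$net_benefit[d$model == nm],
                    col = i)
  }
  graphics::legend("topright", legend = unique(d$model),
                   col = seq_along(unique(d$model)), lty = 1)
  grDevices::dev.off()
}

#' Subgroup and sensitivity re-analyses of a pipeline run
#'
#' Re-fits the stepwise cause-specific models with a restricted exposure
#' definition, or with the 30% sustained eGFR decline endpoint:
#' \describe{
#'   \item{criterion_iii_only}{AKI restricted to episodes triggered by the
#'     48-hour absolute-rise criterion}
#'   \item{stage1_only}{stage-1 AKI vs no AKI (stages 2-3 dropped)}
#'   \item{recurrent_only}{recurrent AKI vs no AKI (single episodes dropped)}
#'   \item{decline30_endpoint}{rebuilds the cohort with the alternative
#'     endpoint and refits the base ladder}
#' }
#'
#' @param run a `pipeline_run`
#' @param which subgroup name
#' @return the amended HR table (or `NULL`, with a warning, when the
#'   subgroup is empty)
#' @export
subgroup_suite <- function(run, which = c("criterion_iii_only",
                                          "stage1_only", "recurrent_only",
                                          "decline30_endpoint")) {
  which <- match.arg(which)
  rows <- run$rows
  if (which == "decline30_endpoint") {
    patients <- read.csv(file.path(run$out_dir, "patients.csv"))
    labs <- read.csv(file.path(run$out_dir, "labs.csv"))
    events <- read.csv(file.path(run$out_dir, "events.csv"))
    rows30 <- build_landmark_cohort(patients, labs, events,
                                    config = detector_config_from(run$config),
                                    endpoint = "decline30")
    return(stepwise_hr_table(rows30))
  }
  sub <- switch(which,
    criterion_iii_only = rows[rows$aki_criterion_iii == 1 |
                                rows$aki_2yr == 0, , drop = FALSE],
    stage1_only = rows[(rows$aki_2yr == 1 & rows$aki_stage_max == 1) |
                         rows$aki_2yr == 0, , drop = FALSE],
    recurrent_only = rows[rows$aki_recurrent == 1 | rows$aki_2yr == 0, ,
                          drop = FALSE])
  exposure <- switch(which,
    criterion_iii_only = "aki_criterion_iii",
    stage1_only = "aki_2yr",
    recurrent_only = "aki_recurrent")
  if (!any(sub[[exposure]] == 1)) {
    warning("empty subgroup '", which, "'; skipped")
    return(NULL)
  }
  stepwise_hr_table(sub, exposure = exposure)
}

#' Command-line entry point
#'
#' Verbs: `all` (full pipeline), `generate`, `landmark`, `fit`, `validate`,
#' `report` (single stages reusing cached artifacts). Flags: `--config`,
#' `--seed`, `--out`, `--print-equation`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`
#' @return exit status (0 on success), invisibly
#' @export
renalrisk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: renalrisk <all|generate|landmark|fit|validate|report> ",
            "--config cfg.json --out dir [--seed n] [--print-equation]")
    return(invisible(1L))
  }
  verb <- args[1]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  config <- get_opt("--config")
  out <- get_opt("--out", "renalrisk_out")
  seed <- get_opt("--seed")
  seed <- if (is.null(seed)) NULL else as.integer(seed)
  if (is.null(config)) stop("--config is required")
  stages <- switch(verb,
    all = c("generate", "landmark", "fit", "validate", "report"),
    generate = "generate", landmark = "landmark", fit = "fit",
    validate = "validate", report = c("validate", "report"),
    stop("unknown verb: ", verb))
  run <- run_pipeline(config, out, seed = seed, stages = stages)
  if ("--print-equation" %in% args && !is.null(run$tables$table4))
    cat(paste(run$tables$table4$model, "=", run$tables$table4$equation,
              collapse = "\n"), "\n")
  invisible(0L)
}
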