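# Discrimination, calibration and decision-curve evaluation of 5-year risk
# predictions under competing risks. The binary 5-year outcome is the
# determinate status: kidney failure by 5 years vs known event-free at 5
# years; death before kidney failure counts as "no event" (the prediction
# target of the Fine-Gray models is cumulative incidence).

#' Build (prediction, 5-year outcome) pairs from landmark rows
#'
#' @param rows landmark rows (`event`, `time_years`)
#' @param risk predicted 5-year risks aligned with `rows`
#' @param horizon_years horizon defining the binary status
#' @return data.frame(risk, outcome, determinate); `determinate` is FALSE
#'   only for subjects censored before the horizon
#' @export
outcome_pairs <- function(rows, risk, horizon_years = 5) {
  stopifnot(length(risk) == nrow(rows))
  outcome <- as.integer(rows$event == "kidney_failure" &
                          rows$time_years <= horizon_years)
  determinate <- rows$event != "censored" |
    rows$time_years >= horizon_years
  data.frame(risk = risk, outcome = outcome, determinate = determinate)
}

drop_indeterminate <- function(pairs) {
  n_drop <- sum(!pairs$determinate)
  if (n_drop) message(n_drop, " indeterminate pair(s) excluded")
  pairs[pairs$determinate, , drop = FALSE]
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Concordance of predictions against the binary 5-year outcome with ties
#' counted 1/2; only determinate pairs enter.
#'
#' @param pairs from [outcome_pairs()]
#' @return AUC in [0, 1]
#' @export
auc <- function(pairs) {
  pairs <- drop_indeterminate(pairs)
  n1 <- sum(pairs$outcome == 1); n0 <- sum(pairs$outcome == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc: need at least one event and one non-event")
  r <- rank(pairs$risk, ties.method = "average")
  (sum(r[pairs$outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components via midranks
delong_components <- function(risk, outcome) {
  x <- risk[outcome == 1]; y <- risk[outcome == 0]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_x) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1
  list(auc = sum(r_all[seq_len(n1)]) / (n1 * n0) - (n1 + 1) / (2 * n0),
       v10 = v10, v01 = v01)
}

#' Paired AUC comparison (DeLong)
#'
#' Compares the AUCs of two prediction vectors on the same subjects using
#' the DeLong paired variance estimate; two-sided p-value. Identical
#' prediction vectors give dAUC = 0, p = 1.
#'
#' @param pairs_a,pairs_b [outcome_pairs()] on identical subjects (same
#'   outcomes in the same order)
#' @return list(auc_a, auc_b, delta, se, z, p_value)
#' @export
compare_auc <- function(pairs_a, pairs_b) {
  if (nrow(pairs_a) != nrow(pairs_b) ||
      any(pairs_a$outcome != pairs_b$outcome) ||
      any(pairs_a$determinate != pairs_b$determinate))
    stop("compare_auc: inputs must be paired on identical subjects")
  keep <- pairs_a$determinate
  a <- delong_components(pairs_a$risk[keep], pairs_a$outcome[keep])
  b <- delong_components(pairs_b$risk[keep], pairs_b$outcome[keep])
  n1 <- length(a$v10); n0 <- length(a$v01)
  s10 <- stats::var(cbind(a$v10, b$v10))
  s01 <- stats::var(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- a$auc - b$auc
  if (v <= 0 || isTRUE(all.equal(delta, 0)) && v < 1e-16) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, delta = delta,
       se = sqrt(max(v, 0)), z = z, p_value = p)
}

#' Calibration report: deciles of predicted risk and calibration slope
#'
#' Bins subjects into tenths of predicted risk (mean predicted vs observed
#' event proportion) and estimates the calibration slope as the coefficient
#' of the model's linear predictor in a one-covariate Fine-Gray model for
#' kidney failure (death competing), with a Wald 95% CI. A slope of 1
#' indicates well-spread predictions; < 1, predictions too extreme.
#'
#' @param pairs from [outcome_pairs()]
#' @param lp linear predictors aligned with `pairs`
#' @param rows landmark rows aligned with `pairs` (needed for the
#'   competing-risk slope)
#' @param n_bins number of bins (default 10)
#' @return list(bins, slope, slope_ci, n)
#' @export
calibration <- function(pairs, lp, rows, n_bins = 10) {
  stopifnot(length(lp) == nrow(pairs), nrow(rows) == nrow(pairs))
  if (any(!is.finite(lp))) stop("calibration: linear predictor must be finite")
  keep <- pairs$determinate
  risk <- pairs$risk
  br <- unique(quantile(risk, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < n_bins + 1)
    warning("fewer than ", n_bins,
            " distinct prediction quantiles; using coarser bins")
  bin <- cut(risk, breaks = br, include.lowest = TRUE, labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- bin == b & keep
    data.frame(bin = b, mean_predicted = mean(risk[bin == b]),
               observed_proportion = mean(pairs$outcome[s]),
               n = sum(bin == b))
  }))
  slope_rows <- rows
  slope_rows$.lp <- lp
  sfit <- fit_fine_gray(slope_rows, list(cov_term(".lp", name = "lp")),
                        "kidney_failure")
  slope <- unname(sfit$coefficients["lp"])
  se <- unname(sfit$se["lp"])
  list(bins = bins, slope = slope,
       slope_ci = c(slope - 1.96 * se, slope + 1.96 * se),
       n = nrow(pairs))
}

#' Decision curve analysis (net benefit)
#'
#' For each risk threshold p_t, treating everyone with predicted risk >=
#' p_t yields net benefit `TP/n - (FP/n) * p_t/(1 - p_t)`. Reference
#' strategies: treat-all (everyone treated) and treat-none (net benefit 0).
#' The default grid spans 0-10% in 0.1% steps.
#'
#' @param predictions named list of risk vectors (one per model), or a
#'   single vector
#' @param pairs [outcome_pairs()] supplying outcomes (and alignment)
#' @param thresholds threshold grid in `[0, 0.99]`
#' @return data.frame(threshold, model, net_benefit, tp, fp, n)
#' @export
decision_curve <- function(predictions, pairs,
                           thresholds = seq(0, 0.10, by = 0.001)) {
  if (!is.list(predictions)) predictions <- list(model = predictions)
  if (any(thresholds < 0 | thresholds > 0.99))
    stop("thresholds must lie in [0, 0.99]")
  keep <- pairs$determinate
  y <- pairs$outcome[keep]
  n <- length(y)
  preds <- c(lapply(predictions, function(p) p[keep]),
             list(treat_all = rep(1, n), treat_none = rep(-1, n)))
  out <- list()
  for (nm in names(preds)) {
    p <- preds[[nm]]
    stopifnot(length(p) == n)
    for (pt in thresholds) {
      treat <- p >= pt
      tp <- sum(treat & y == 1); fp <- sum(treat & y == 0)
      nb <- tp / n - (fp / n) * pt / (1 - pt)
      out[[length(out) + 1]] <- data.frame(
        threshold = pt, model = nm, net_benefit = nb, tp = tp, fp = fp,
        n = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
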