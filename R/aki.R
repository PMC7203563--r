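#' AKI detector configuration
#'
#' Settings for the three-criterion KDIGO-based creatinine e-alert detector.
#' A measurement at day t triggers AKI when any enabled criterion holds:
#' \describe{
#'   \item{i}{scr >= `ratio_threshold` x median of all creatinine values 8-90
#'     days before t (or 91-365 days before t if no tests fall in 8-90 days);}
#'   \item{ii}{scr >= `ratio_threshold` x lowest creatinine within the
#'     previous 7 days;}
#'   \item{iii}{scr more than `rapid_rise` umol/L above the lowest creatinine
#'     within the previous 48 h.}
#' }
#' Consecutive triggers closer than `recurrence_gap_days` are merged into a
#' single episode; the gap is a configurable convention (default 30 days)
#' because no standard defines when triggers become a distinct recurrence.
#'
#' @param ratio_threshold ratio for criteria i/ii (default 1.5)
#' @param medium_window days-before-index window for the criterion-i median
#' @param fallback_window fallback window when `medium_window` holds no tests
#' @param short_window lookback (days) for criterion ii
#' @param rapid_window lookback (days) for criterion iii (48 h = 2 days)
#' @param rapid_rise absolute creatinine rise for criterion iii, umol/L
#' @param criteria_enabled subset of c("i","ii","iii")
#' @param recurrence_gap_days merge gap between triggers, days
#' @param stage2_ratio,stage3_ratio,stage3_scr staging thresholds: stage 3 if
#'   peak ratio >= `stage3_ratio` or peak creatinine >= `stage3_scr` umol/L,
#'   stage 2 if peak ratio in `[stage2_ratio, stage3_ratio)`, else stage 1
#' @return list of class `aki_config`
#' @export
aki_config <- function(ratio_threshold = 1.5,
                       medium_window = c(8, 90),
                       fallback_window = c(91, 365),
                       short_window = 7,
                       rapid_window = 2,
                       rapid_rise = 26,
                       criteria_enabled = c("i", "ii", "iii"),
                       recurrence_gap_days = 30,
                       stage2_ratio = 2,
                       stage3_ratio = 3,
                       stage3_scr = 353.6) {
  stopifnot(
    ratio_threshold > 0, rapid_rise > 0, recurrence_gap_days > 0,
    length(medium_window) == 2, length(fallback_window) == 2,
    medium_window[1] < medium_window[2],
    fallback_window[1] < fallback_window[2],
    medium_window[2] < fallback_window[1],
    short_window > 0, rapid_window > 0, rapid_window <= short_window,
    short_window < medium_window[1]
  )
  criteria_enabled <- match.arg(criteria_enabled, c("i", "ii", "iii"),
                                several.ok = TRUE)
  structure(list(
    ratio_threshold = ratio_threshold, medium_window = medium_window,
    fallback_window = fallback_window, short_window = short_window,
    rapid_window = rapid_window, rapid_rise = rapid_rise,
    criteria_enabled = criteria_enabled,
    recurrence_gap_days = recurrence_gap_days,
    stage2_ratio = stage2_ratio, stage3_ratio = stage3_ratio,
    stage3_scr = stage3_scr
  ), class = "aki_config")
}

check_series <- function(series) {
  if (!all(c("day", "scr") %in% names(series)))
    stop("a lab series needs columns 'day' and 'scr'")
  if (nrow(series) == 0) return(series)
  series <- series[order(series$day), , drop = FALSE]
  if (any(duplicated(series$day)))
    series <- series[!duplicated(series$day), , drop = FALSE]
  if (any(series$scr <= 0)) stop("creatinine must be positive")
  series
}

#' Reference creatinine values for one index measurement
#'
#' Computes the three lookback references used by the AKI criteria at
#' `index_day`: the medium-window median (with fallback), the 7-day minimum,
#' and the 48-hour minimum. Windows are strictly prior to the index day.
#'
#' @param series data.frame with columns `day` (integer days) and `scr`
#'   (umol/L) for one patient
#' @param index_day day of an existing measurement
#' @param config [aki_config()]
#' @return list(ref_median, ref_min7, ref_min48); `NA` when a window is empty
#' @export
reference_creatinine <- function(series, index_day, config = aki_config()) {
  series <- check_series(series)
  if (!index_day %in% series$day)
    stop("index_day does not correspond to a measurement")
  lag <- index_day - series$day
  med_vals <- series$scr[lag >= config$medium_window[1] &
                         lag <= config$medium_window[2]]
  if (!length(med_vals))
    med_vals <- series$scr[lag >= config$fallback_window[1] &
                           lag <= config$fallback_window[2]]
  min_over <- function(w) {
    v <- series$scr[lag > 0 & lag <= w]
    if (length(v)) min(v) else NA_real_
  }
  list(
    ref_median = if (length(med_vals)) median(med_vals) else NA_real_,
    ref_min7 = min_over(config$short_window),
    ref_min48 = min_over(config$rapid_window)
  )
}

# stage for a merged episode
aki_stage <- function(peak_ratio, peak_scr, config) {
  if (peak_ratio >= config$stage3_ratio || peak_scr >= config$stage3_scr) 3L
  else if (peak_ratio >= config$stage2_ratio) 2L
  else 1L
}

#' Detect AKI episodes in a creatinine series
#'
#' Applies the three-criterion e-alert to every measurement inside `window`,
#' records the lowest-numbered satisfied criterion per trigger, and merges
#' consecutive triggers separated by less than `recurrence_gap_days` into
#' episodes. `peak_ratio` is the maximum triggering creatinine of the episode
#' divided by the reference of the first trigger's criterion; staging follows
#' standard KDIGO thresholds (see [aki_config()]).
#'
#' Detection starts at the second measurement: the first has no reference.
#'
#' @inheritParams reference_creatinine
#' @param window `c(start_day, end_day)` restricting trigger days (references
#'   may still use earlier measurements)
#' @return data.frame with columns onset_day, end_day, trigger_criterion,
#'   peak_ratio, stage; zero rows when nothing triggers
#' @export
detect_aki <- function(series, window = NULL, config = aki_config()) {
  series <- check_series(series)
  empty <- data.frame(onset_day = numeric(), end_day = numeric(),
                      trigger_criterion = character(),
                      peak_ratio = numeric(), stage = integer(),
                      stringsAsFactors = FALSE)
  m <- nrow(series)
  if (m < 2) return(empty)
  if (is.null(window)) window <- range(series$day)
  d <- series$day; s <- series$scr
  # no measurement can trigger when the global range rules out all criteria
  # (every reference is >= min(s), so criteria i/ii need max/min >= threshold)
  if (max(s) < config$ratio_threshold * min(s) &&
      max(s) - min(s) <= config$rapid_rise)
    return(empty)
  trig_day <- numeric(); trig_crit <- character()
  trig_ref <- numeric(); trig_scr <- numeric()
  on <- "i" %in% config$criteria_enabled
  on2 <- "ii" %in% config$criteria_enabled
  on3 <- "iii" %in% config$criteria_enabled
  for (j in 2:m) {
    if (d[j] < window[1] || d[j] > window[2]) next
    lag <- d[j] - d
    med_vals <- s[lag >= config$medium_window[1] & lag <= config$medium_window[2]]
    if (!length(med_vals))
      med_vals <- s[lag >= config$fallback_window[1] & lag <= config$fallback_window[2]]
    ref_median <- if (length(med_vals)) median(med_vals) else NA_real_
    v7 <- s[lag > 0 & lag <= config$short_window]
    ref_min7 <- if (length(v7)) min(v7) else NA_real_
    v48 <- s[lag > 0 & lag <= config$rapid_window]
    ref_min48 <- if (length(v48)) min(v48) else NA_real_
    crit <- ref <- NULL
    if (on && !is.na(ref_median) && s[j] >= config$ratio_threshold * ref_median) {
      crit <- "i"; ref <- ref_median
    } else if (on2 && !is.na(ref_min7) && s[j] >= config$ratio_threshold * ref_min7) {
      crit <- "ii"; ref <- ref_min7
    } else if (on3 && !is.na(ref_min48) && s[j] - ref_min48 > config$rapid_rise) {
      crit <- "iii"; ref <- ref_min48
    }
    if (!is.null(crit)) {
      trig_day <- c(trig_day, d[j]); trig_crit <- c(trig_crit, crit)
      trig_ref <- c(trig_ref, ref); trig_scr <- c(trig_scr, s[j])
    }
  }
  if (!length(trig_day)) return(empty)
  grp <- cumsum(c(1, diff(trig_day) >= config$recurrence_gap_days))
  out <- lapply(split(seq_along(trig_day), grp), function(ix) {
    peak <- max(trig_scr[ix])
    ratio <- peak / trig_ref[ix[1]]
    data.frame(onset_day = trig_day[ix[1]], end_day = trig_day[ix[length(ix)]],
               trigger_criterion = trig_crit[ix[1]], peak_ratio = ratio,
               stage = aki_stage(ratio, peak, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise AKI exposure from detected episodes
#'
#' @param episodes data.frame from [detect_aki()]
#' @param config [aki_config()] (unused beyond interface symmetry; merging
#'   already happened at detection time)
#' @return list(aki_2yr, aki_recurrent, aki_stage_max); stage is `NA` without
#'   episodes
#' @export
classify_recurrence <- function(episodes, config = aki_config()) {
  n <- if (is.null(episodes)) 0L else nrow(episodes)
  list(
    aki_2yr = as.integer(n >= 1),
    aki_recurrent = as.integer(n >= 2),
    aki_stage_max = if (n) max(episodes$stage) else NA_integer_
  )
}
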