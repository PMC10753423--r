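# Longitudinal derived variables: change detection against consensus limits
# ("lose at least 10% of body weight within 6 months") and trend
# classification, so that longitudinal criteria become ordinary predicates on
# materialized boolean/categorical variables and the rule engine stays purely
# propositional.

#' Create a timestamped series
#'
#' @param var_id id of the time-series variable the points belong to.
#' @param time vector coercible to `Date`; must be strictly increasing.
#' @param value numeric values, in the variable's declared units.
#' @return list of class `rc_series`.
#' @export
rc_series <- function(var_id, time, value) {
  time <- as.Date(time)
  value <- as.numeric(value)
  stopifnot(length(time) == length(value))
  if (anyNA(time) || anyNA(value)) stop("series '", var_id, "': NA timestamps or values")
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0)) {
    stop("series '", var_id, "': timestamps must be strictly increasing")
  }
  structure(list(var_id = var_id, time = time, value = value), class = "rc_series")
}

#' Specify a longitudinal change limit
#'
#' @param mode `"relative_percent"` (change expressed as percent of the
#'   earlier value) or `"absolute"` (change in the variable's units).
#' @param direction `"decrease"`, `"increase"` or `"either"`.
#' @param threshold positive number: percent for relative mode, variable
#'   units for absolute mode.
#' @param window_months,window_days window length; exactly one must be given.
#'   Months are calendar months (day-of-month clamped), the clinically usual
#'   reading of phrases like "within 6 months"; use days for a fixed-length
#'   window.
#' @return list of class `rc_change_spec`.
#' @export
change_spec <- function(mode = c("relative_percent", "absolute"),
                        direction = c("decrease", "increase", "either"),
                        threshold, window_months = NULL, window_days = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (is.null(window_months) == is.null(window_days)) {
    stop("specify exactly one of window_months or window_days")
  }
  if (!is.null(window_months)) stopifnot(window_months > 0) else stopifnot(window_days > 0)
  structure(list(mode = mode, direction = direction, threshold = threshold,
                 window_months = window_months, window_days = window_days),
            class = "rc_change_spec")
}

days_in_month <- function(year, month) {
  d <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, d)
}

add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + n
  yr <- m0 %/% 12L
  mo <- m0 %% 12L
  day <- pmin(lt$mday, days_in_month(yr + 1900L, mo + 1L))
  as.Date(sprintf("%04d-%02d-%02d", yr + 1900L, mo + 1L, day))
}

pair_in_window <- function(t1, t2, spec) {
  if (!is.null(spec$window_months)) {
    t2 <= add_months(t1, spec$window_months)
  } else {
    as.numeric(t2 - t1) <= spec$window_days
  }
}

#' Detect a significant longitudinal change
#'
#' Evaluates every ordered pair of observations `(t1, t2)` with
#' `t2 <= as_of` and `t2 - t1` within the window; the flag is `TRUE` iff any
#' pair meets the configured direction and threshold (a patient-state
#' property: any qualifying pair counts, not only the endpoints). Relative
#' change is `(v2 - v1) / v1 * 100`; pairs with `v1 = 0` in relative mode
#' cannot be evaluated and are skipped (recorded in the `skipped` field).
#' With fewer than two observations at or before `as_of` the result is
#' unknown (`NA`).
#'
#' @param series an [rc_series()].
#' @param spec a [change_spec()].
#' @param as_of evaluation time (coercible to `Date`); observations after
#'   `as_of` are ignored.
#' @return list with `flag` (`TRUE`/`FALSE`/`NA`), `magnitude` (the most
#'   extreme change in the configured direction over all evaluated pairs, in
#'   percent or units; `NULL` when no pair could be evaluated), `span` (the
#'   `(t1, t2)` of the extreme pair, or `NULL`) and `skipped` (number of
#'   pairs skipped for `v1 = 0`).
#' @export
#' @examples
#' s <- rc_series("weight", c("2023-01-01", "2023-06-01"), c(80, 72))
#' detect_change(s, change_spec("relative_percent", "decrease", 10,
#'                              window_months = 6), as_of = "2023-06-01")
detect_change <- function(series, spec, as_of) {
  stopifnot(inherits(series, "rc_series"), inherits(spec, "rc_change_spec"))
  as_of <- as.Date(as_of)
  keep <- series$time <= as_of
  t <- series$time[keep]
  v <- series$value[keep]
  n <- length(t)
  if (n < 2L) {
    return(list(flag = NA, magnitude = NULL, span = NULL, skipped = 0L))
  }
  best <- NULL
  best_span <- NULL
  skipped <- 0L
  flag <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!pair_in_window(t[i], t[j], spec)) next
      if (spec$mode == "relative_percent") {
        if (v[i] == 0) { skipped <- skipped + 1L; next }
        delta <- (v[j] - v[i]) / v[i] * 100
      } else {
        delta <- v[j] - v[i]
      }
      qualifies <- switch(spec$direction,
        decrease = delta <= -spec$threshold,
        increase = delta >= spec$threshold,
        either = abs(delta) >= spec$threshold)
      if (qualifies) flag <- TRUE
      extremity <- switch(spec$direction,
        decrease = -delta, increase = delta, either = abs(delta))
      if (is.null(best) || extremity > best$extremity) {
        best <- list(extremity = extremity, delta = delta)
        best_span <- c(t[i], t[j])
      }
    }
  }
  if (is.null(best)) {
    # observations exist but no pair fell inside the window (or all skipped)
    return(list(flag = if (skipped > 0L) NA else FALSE,
                magnitude = NULL, span = NULL, skipped = skipped))
  }
  list(flag = flag, magnitude = best$delta, span = best_span, skipped = skipped)
}

#' Classify the trend of a series
#'
#' Ordinary least-squares slope of the observations inside the window ending
#' at `as_of`. Slopes whose total in-window movement is below a dead band
#' (a fraction of the in-window value range, default 5% per window) classify
#' as `"stable"`; otherwise the slope sign maps to `"improving"` /
#' `"worsening"` according to whether higher values are clinically better
#' for the variable. Fewer than 3 in-window observations give `"unknown"`.
#'
#' @param series an [rc_series()].
#' @param window_days window length in days (the window is
#'   `[as_of - window_days, as_of]`).
#' @param as_of evaluation time.
#' @param higher_is_better logical: does a rising value mean improvement?
#' @param dead_band fraction of the in-window value range per window below
#'   which the movement counts as stable (default 0.05).
#' @return one of `"improving"`, `"stable"`, `"worsening"`, `"unknown"`.
#' @export
series_trend <- function(series, window_days, as_of, higher_is_better = TRUE,
                         dead_band = 0.05) {
  stopifnot(inherits(series, "rc_series"))
  as_of <- as.Date(as_of)
  keep <- series$time <= as_of & series$time >= as_of - window_days
  t <- as.numeric(series$time[keep])
  v <- series$value[keep]
  if (length(t) < 3L) return("unknown")
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) return("stable")
  slope <- sum(tc * (v - mean(v))) / denom   # units per day
  rng <- diff(range(v))
  threshold <- dead_band * rng / window_days
  if (abs(slope) <= threshold) return("stable")
  up <- slope > 0
  if (up == isTRUE(higher_is_better)) "improving" else "worsening"
}

#' Materialize derived variables into a patient record
#'
#' For every KB variable carrying a `derived` specification, computes its
#' value from the patient's series (change flag or trend class) and stores it
#' in the record under the variable's own id, so rule evaluation stays purely
#' propositional. A change flag of `NA` or a trend of `"unknown"` leaves the
#' variable missing; an absent source series also leaves it missing.
#'
#' @param kb a knowledge base.
#' @param patient a [patient_record()].
#' @param as_of evaluation time (default: the latest timestamp across the
#'   patient's series, or today when there is none).
#' @return the patient record with derived values filled in.
#' @export
materialize_derived <- function(kb, patient, as_of = NULL) {
  stopifnot(inherits(patient, "rc_patient"))
  series_by_var <- stats::setNames(patient$series,
                                   vapply(patient$series, `[[`, "", "var_id"))
  if (is.null(as_of)) {
    all_t <- unlist(lapply(patient$series, function(s) as.numeric(s$time)))
    as_of <- if (length(all_t)) as.Date(max(all_t), origin = "1970-01-01") else Sys.Date()
  }
  for (v in kb$variables) {
    if (is.null(v$derived)) next
    s <- series_by_var[[v$derived$series_var]]
    if (is.null(s)) next
    d <- v$derived
    if (identical(d$type, "change")) {
      spec <- change_spec(d$mode, d$direction, d$threshold,
                          window_months = d$window_months,
                          window_days = d$window_days)
      res <- detect_change(s, spec, as_of)
      if (!is.na(res$flag)) patient$values[[v$var_id]] <- res$flag
    } else if (identical(d$type, "trend")) {
      cls <- series_trend(s, d$window_days, as_of,
                          higher_is_better = isTRUE(d$higher_is_better),
                          dead_band = d$dead_band %||% 0.05)
      if (cls != "unknown") patient$values[[v$var_id]] <- cls
    }
  }
  patient
}
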