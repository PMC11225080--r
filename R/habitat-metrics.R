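#' Read / write hourly temperature-logger series
#'
#' Logger CSVs have columns `timestamp_iso8601, temp_c`. Timestamps must be
#' strictly increasing; gaps longer than two hours are flagged via the
#' `"gaps"` attribute.
#'
#' @param path CSV file path.
#' @param site Optional site label attached as an attribute.
#' @return A `logger_series` data frame with `timestamp` (POSIXct, UTC) and
#'   `temp_c`.
#' @export
read_logger_series <- function(path, site = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_logger_series(parse_iso8601(raw$timestamp_iso8601), raw$temp_c,
                   site = site)
}

#' @rdname read_logger_series
#' @param series A `logger_series`.
#' @export
write_logger_series <- function(series, path) {
  utils::write.csv(
    data.frame(timestamp_iso8601 = format_iso8601(series$timestamp),
               temp_c = series$temp_c),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

as_logger_series <- function(timestamp, temp_c, site = NULL) {
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("logger timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(temp_c))) {
    stop("logger temperatures must be finite", call. = FALSE)
  }
  out <- data.frame(timestamp = timestamp, temp_c = temp_c)
  gaps <- which(diff(as.numeric(timestamp)) > 2 * 3600)
  attr(out, "site") <- site
  attr(out, "gaps") <- gaps
  class(out) <- c("logger_series", "data.frame")
  out
}

clip_period <- function(x, period, what = "timestamp") {
  if (is.null(period)) return(x)
  period <- as.Date(period)
  if (length(period) != 2L || period[2] < period[1]) {
    stop("`period` must be c(start_date, end_date)", call. = FALSE)
  }
  key <- if (what == "date") x$date else as.Date(x$timestamp, tz = "UTC")
  x[key >= period[1] & key <= period[2], , drop = FALSE]
}

#' Daily mean / minimum / maximum temperatures
#'
#' Collapses an hourly logger series to per-calendar-date statistics (dates in
#' the logger's time zone, UTC here). Days with fewer than the expected 24
#' readings are kept but flagged in the `n` column; empty days simply do not
#' appear.
#'
#' @param series A `logger_series`.
#' @param period Optional `c(start_date, end_date)` (Date or string) clip.
#' @return Data frame with `date`, `mean`, `min`, `max`, `n`.
#' @export
daily_summaries <- function(series, period = NULL) {
  s <- clip_period(series, period)
  if (!nrow(s)) stop("no readings in the requested period", call. = FALSE)
  date <- as.Date(s$timestamp, tz = "UTC")
  agg <- function(f) tapply(s$temp_c, date, f)
  m <- agg(mean)
  out <- data.frame(
    date = as.Date(names(m)),
    mean = as.numeric(m),
    min = as.numeric(agg(min)),
    max = as.numeric(agg(max)),
    n = as.integer(tapply(s$temp_c, date, length))
  )
  rownames(out) <- NULL
  if (any(out$n < 24)) {
    warning(sprintf("%d day(s) have fewer than 24 readings", sum(out$n < 24)),
            call. = FALSE)
  }
  out
}

#' 7-day sliding average of a daily statistic (7DADMean / 7DADMax / 7DADMin)
#'
#' Moving average over seven consecutive days of the chosen daily statistic,
#' using only windows fully contained in the supplied daily table (a 31-day
#' month yields 25 windows). The period summary (e.g. "August mean 7DADMax")
#' is the mean of all window values.
#'
#' @param daily Daily table from [daily_summaries()].
#' @param statistic One of `"mean"`, `"max"`, `"min"`.
#' @return List with `windows` (data frame `start_date`, `end_date`, `value`)
#'   and `period_mean`.
#' @export
sliding_7day <- function(daily, statistic = c("mean", "max", "min")) {
  statistic <- match.arg(statistic)
  x <- daily[[statistic]]
  n <- length(x)
  if (n < 7) stop("need at least 7 days for a 7-day sliding average",
                  call. = FALSE)
  vals <- as.numeric(stats::filter(x, rep(1 / 7, 7), sides = 1))[7:n]
  list(
    windows = data.frame(
      start_date = daily$date[seq_len(n - 6L)],
      end_date = daily$date[7:n],
      value = vals
    ),
    period_mean = mean(vals)
  )
}

#' Mean diel temperature range (Daily Max-Min)
#'
#' Daily maximum minus daily minimum, averaged over the period.
#'
#' @param daily Daily table from [daily_summaries()].
#' @return Mean diel range in degrees C.
#' @export
diel_range <- function(daily) {
  if (!nrow(daily)) stop("empty daily table", call. = FALSE)
  mean(daily$max - daily$min)
}

#' Cumulative degree days over a period
#'
#' Sum of the daily mean temperatures over the period (units degree C * days;
#' a 31-day August averaging 17 degrees C accumulates ~529). Requires complete
#' daily coverage of the period.
#'
#' @param daily Daily table from [daily_summaries()].
#' @param period `c(start_date, end_date)`; defaults to the span of `daily`.
#' @return Cumulative degree days.
#' @export
cumulative_degree_days <- function(daily, period = NULL) {
  if (is.null(period)) period <- range(daily$date)
  period <- as.Date(period)
  d <- clip_period(daily, period, what = "date")
  expected <- seq(period[1], period[2], by = "day")
  missing <- setdiff(as.character(expected), as.character(d$date))
  if (length(missing)) {
    stop(sprintf("missing daily coverage: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sum(d$mean)
}

#' Cumulative degree hours over a period
#'
#' Sum of the hourly readings over the period (degree C * hours). On a
#' constant series this is exactly 24 times the cumulative degree days. The
#' cadence is checked: spacing away from one hour raises an error when
#' `strict`, otherwise a warning.
#'
#' @param series A `logger_series`.
#' @param period Optional `c(start_date, end_date)` clip.
#' @param strict Error (default) or warn on non-hourly cadence.
#' @return Cumulative degree hours.
#' @export
cumulative_degree_hours <- function(series, period = NULL, strict = TRUE) {
  s <- clip_period(series, period)
  if (!nrow(s)) stop("no readings in the requested period", call. = FALSE)
  dt <- diff(as.numeric(s$timestamp))
  if (length(dt) && any(abs(dt - 3600) > 1)) {
    msg <- "logger cadence is not hourly; degree hours assume hourly readings"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  sum(s$temp_c)
}

#' Exposure of daily and hourly temperatures to a reference interval
#'
#' For each daily statistic (mean, min, max): the number of days strictly
#' below `interval[1]`, within the closed interval, and strictly above
#' `interval[2]`; plus the number of hourly readings above the upper bound and
#' within the interval. Interval membership is inclusive at both ends.
#'
#' @param daily Daily table from [daily_summaries()].
#' @param series Matching `logger_series` (for the hourly counts).
#' @param interval `c(lo, hi)` in degrees C, e.g. a Topt90 range.
#' @return List: `days` (data frame `statistic`, `below`, `within`, `above`),
#'   `hours_above`, `hours_within`.
#' @export
threshold_exposure <- function(daily, series, interval) {
  if (length(interval) != 2L || interval[1] > interval[2]) {
    stop("`interval` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  lo <- interval[1]; hi <- interval[2]
  per_stat <- function(x) {
    c(below = sum(x < lo), within = sum(x >= lo & x <= hi),
      above = sum(x > hi))
  }
  days <- as.data.frame(t(vapply(
    daily[c("mean", "min", "max")], per_stat, c(below = 0, within = 0, above = 0)
  )))
  days <- cbind(statistic = rownames(days), days)
  rownames(days) <- NULL
  s <- clip_period(series, range(daily$date))
  list(
    days = days,
    hours_above = sum(s$temp_c > hi),
    hours_within = sum(s$temp_c >= lo & s$temp_c <= hi)
  )
}

#' Winter-season freezing statistics
#'
#' The winter season is bounded by the first date after 1 September with a
#' sub-freezing daily minimum and the last such date before 1 June of the
#' following year. When the site never freezes, a fixed 11 November -- 16
#' April window is used instead (`fallback = TRUE` in the result). Within the
#' season the function counts days whose minimum (and maximum) stayed at or
#' below 0 degrees C, and reports the lowest February daily minimum.
#'
#' @param daily Daily table spanning at least November through April.
#' @return List: `season_start`, `season_end`, `fallback`, `days_min_le0`,
#'   `days_max_le0`, `february_min`.
#' @export
winter_metrics <- function(daily) {
  dts <- daily$date
  first_year <- as.integer(format(min(dts), "%Y"))
  # the winter under study starts in the year that contains the first November
  nov_dates <- dts[format(dts, "%m") == "11"]
  if (!length(nov_dates)) stop("series does not span November", call. = FALSE)
  y0 <- as.integer(format(min(nov_dates), "%Y"))
  apr_end <- as.Date(sprintf("%d-04-30", y0 + 1L))
  if (max(dts) < apr_end) {
    stop("series must span November through April", call. = FALSE)
  }
  sep1 <- as.Date(sprintf("%d-09-01", y0))
  jun1 <- as.Date(sprintf("%d-06-01", y0 + 1L))
  candidate <- daily[dts > sep1 & dts < jun1 & daily$min <= 0, , drop = FALSE]
  if (nrow(candidate)) {
    season <- c(min(candidate$date), max(candidate$date))
    fallback <- FALSE
  } else {
    season <- c(as.Date(sprintf("%d-11-11", y0)),
                as.Date(sprintf("%d-04-16", y0 + 1L)))
    fallback <- TRUE
  }
  in_season <- daily[dts >= season[1] & dts <= season[2], , drop = FALSE]
  feb <- daily[format(dts, "%m") == "02" &
                 as.integer(format(dts, "%Y")) == y0 + 1L, , drop = FALSE]
  list(
    season_start = season[1],
    season_end = season[2],
    fallback = fallback,
    days_min_le0 = sum(in_season$min <= 0),
    days_max_le0 = sum(in_season$max <= 0),
    february_min = if (nrow(feb)) min(feb$min) else NA_real_,
    winter_year = y0
  )
}

#' Thermal safety margin of a population in its habitat
#'
#' Distance between the upper limit of the population's Topt90 range and a
#' habitat maximum-temperature estimate: `tsm_max` uses the August hourly
#' maximum, `tsm_7dadmax` the August mean 7DADMax. Negative margins mean the
#' habitat already exceeds the optimum breadth.
#'
#' @param topt90_upper Upper limit of the Topt90 range, degrees C.
#' @param august_max August maximum hourly temperature, degrees C.
#' @param august_mean_7dadmax August mean 7DADMax, degrees C.
#' @param site,year Optional labels carried through.
#' @return List with the inputs and `tsm_max`, `tsm_7dadmax` (degrees C).
#' @export
thermal_safety_margin <- function(topt90_upper, august_max,
                                  august_mean_7dadmax,
                                  site = NA_character_, year = NA_integer_) {
  for (v in c(topt90_upper, august_max, august_mean_7dadmax)) {
    stopifnot_scalar_number(v, "TSM input")
  }
  list(
    site = site, year = year,
    topt90_upper = topt90_upper,
    august_max = august_max,
    august_mean_7dadmax = august_mean_7dadmax,
    tsm_max = topt90_upper - august_max,
    tsm_7dadmax = topt90_upper - august_mean_7dadmax
  )
}

#' Full thermal-regime summary for one site and period
#'
#' Composes the regime metrics reported for a summer month: daily table,
#' period maximum, mean 7DADMean/Max/Min, mean diel range, cumulative degree
#' days and hours, and exposure counts against a reference interval (e.g. the
#' population's Topt90 range).
#'
#' @param series A `logger_series`.
#' @param period `c(start_date, end_date)`.
#' @param interval Optional reference interval for [threshold_exposure()].
#' @param site Optional site label.
#' @return List of class `regime_summary`.
#' @export
regime_summary <- function(series, period, interval = NULL, site = NULL) {
  daily <- daily_summaries(series, period)
  out <- list(
    site = if (is.null(site)) attr(series, "site") else site,
    period = as.Date(period),
    daily = daily,
    period_max = max(daily$max),
    mean_7dadmean = sliding_7day(daily, "mean")$period_mean,
    mean_7dadmax = sliding_7day(daily, "max")$period_mean,
    mean_7dadmin = sliding_7day(daily, "min")$period_mean,
    mean_diel_range = diel_range(daily),
    cdd = cumulative_degree_days(daily, period),
    cdh = cumulative_degree_hours(clip_period(series, period), period)
  )
  if (!is.null(interval)) {
    out$interval <- interval
    out$exposure <- threshold_exposure(daily, series, interval)
  }
  class(out) <- c("regime_summary", "list")
  out
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf("<regime_summary %s  %s to %s>\n",
              if (is.null(x$site)) "" else x$site, x$period[1], x$period[2]))
  cat(sprintf("  max = %.1f C, mean 7DADMax = %.1f C, diel range = %.1f C\n",
              x$period_max, x$mean_7dadmax, x$mean_diel_range))
  cat(sprintf("  CDD = %.0f C*days, CDH = %.0f C*hours\n", x$cdd, x$cdh))
  invisible(x)
}
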