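#' Segment a respirometry trace into seal measurement windows
#'
#' Splits the trace at phase-label changes, keeps only seal phases (`seal`
#' overnight, `chase_seal` during the chase protocol), and trims the first
#' `trim_seconds` of each seal to exclude flush-mixing carryover (standard
#' intermittent-respirometry practice; configurable). Windows left with fewer
#' than `min_points` samples are dropped with a warning, never an error.
#'
#' @param trace An `oxygen_trace` (see [read_oxygen_trace()]).
#' @param trim_seconds Seconds discarded at the start of every seal.
#' @param min_points Minimum samples a trimmed window must retain.
#' @return List of `seal_window` data frames, each carrying attributes
#'   `phase` (`"overnight"` or `"chase"`), `window_index`, and `trial_id`.
#' @export
segment_trace <- function(trace, trim_seconds = 60, min_points = 6) {
  stopifnot(inherits(trace, "data.frame"))
  runs <- rle(as.character(trace$phase))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seal_runs <- which(runs$values %in% c("seal", "chase_seal"))
  windows <- list()
  dropped <- 0L
  for (j in seq_along(seal_runs)) {
    r <- seal_runs[j]
    w <- trace[starts[r]:ends[r], , drop = FALSE]
    t0 <- as.numeric(w$timestamp[1])
    w <- w[as.numeric(w$timestamp) - t0 >= trim_seconds, , drop = FALSE]
    if (nrow(w) < min_points) {
      dropped <- dropped + 1L
      next
    }
    attr(w, "phase") <- if (runs$values[r] == "seal") "overnight" else "chase"
    attr(w, "window_index") <- j
    attr(w, "trial_id") <- attr(trace, "trial_id")
    class(w) <- c("seal_window", "data.frame")
    windows[[length(windows) + 1L]] <- w
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d seal window(s) with fewer than %d samples",
                    dropped, min_points), call. = FALSE)
  }
  windows
}

# contiguous near-equal partition of n items into k blocks (sizes differ <= 1)
partition_indices <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

ols_slope <- function(t_min, y) {
  fit <- stats::lm.fit(cbind(1, t_min), y)
  slope <- unname(fit$coefficients[2])
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(slope = slope, r2 = r2)
}

#' Estimate sub-window oxygen-uptake slopes for seal windows
#'
#' Each seal window is partitioned into equal, non-overlapping contiguous
#' sub-windows (2 per overnight seal, 5 per chase seal by default, matching
#' the number of slope measurements each seal type supports) and an ordinary
#' least-squares regression of saturation on time is fit per sub-window. The
#' slope (% saturation min^-1) is converted to a mass uptake rate with
#' [saturation_to_mass_rate()] at the sub-window's mean temperature.
#'
#' Two coefficients of determination are reported for every slope: `sub_r2`,
#' from the sub-window regression itself, and `seal_r2`, from a regression
#' over the whole trimmed seal. The downstream quality filter defaults to the
#' seal-level value: a sub-window spans only a few minutes, so at the coldest
#' test temperatures an honest resting decline carries too little signal per
#' sample for the sub-window statistic to clear a 0.90 threshold, whereas the
#' full seal does (see the methods vignette for the numbers). Sub-windows
#' where the regression would be degenerate (no time variance) raise an
#' error; negative-uptake sub-windows (oxygen increasing) are retained but
#' flagged, to be removed by the downstream quality filter.
#'
#' @param windows A `seal_window` or list of them (from [segment_trace()]).
#' @param volume_l Respirometer water volume, litres.
#' @param pressure_kpa Barometric pressure, kPa.
#' @param n_sub_overnight,n_sub_chase Sub-windows per seal by phase.
#' @return A `slope_table` data frame: `trial_id`, `phase`, `window_index`,
#'   `sub_index`, `slope_sat_pct_min`, `sub_r2`, `seal_r2`, `n`,
#'   `mean_temp_c`, `rate_mg_min`, `flagged`.
#' @export
estimate_slopes <- function(windows, volume_l, pressure_kpa = 101.325,
                            n_sub_overnight = 2, n_sub_chase = 5) {
  if (is.data.frame(windows)) windows <- list(windows)
  rows <- vector("list", 0L)
  for (w in windows) {
    phase <- attr(w, "phase")
    k <- if (identical(phase, "chase")) n_sub_chase else n_sub_overnight
    if (nrow(w) < 3 * k) {
      warning(sprintf(
        "window %s has too few samples for %d sub-windows; skipped",
        attr(w, "window_index"), k), call. = FALSE)
      next
    }
    grp <- partition_indices(nrow(w), k)
    t0 <- as.numeric(w$timestamp[1])
    t_all <- (as.numeric(w$timestamp) - t0) / 60
    seal_r2 <- ols_slope(t_all, w$do_saturation_pct)$r2
    for (g in seq_len(k)) {
      sel <- grp == g
      t_min <- (as.numeric(w$timestamp[sel]) - t0) / 60
      if (stats::var(t_min) == 0) stop("degenerate window", call. = FALSE)
      fit <- ols_slope(t_min, w$do_saturation_pct[sel])
      mean_temp <- mean(w$temp_c[sel])
      rate <- saturation_to_mass_rate(fit$slope, mean_temp, volume_l,
                                      pressure_kpa)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = if (is.null(attr(w, "trial_id"))) NA_character_ else
          attr(w, "trial_id"),
        phase = phase,
        window_index = attr(w, "window_index"),
        sub_index = g,
        slope_sat_pct_min = fit$slope,
        sub_r2 = fit$r2,
        seal_r2 = seal_r2,
        n = sum(sel),
        mean_temp_c = mean_temp,
        rate_mg_min = rate,
        flagged = rate < 0
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = character(), phase = character(),
               window_index = integer(), sub_index = integer(),
               slope_sat_pct_min = numeric(), sub_r2 = numeric(),
               seal_r2 = numeric(), n = integer(),
               mean_temp_c = numeric(), rate_mg_min = numeric(),
               flagged = logical())
  class(out) <- c("slope_table", "data.frame")
  out
}

#' Write / read a slope table CSV
#'
#' Columns: `trial_id, phase, window_index, sub_index, slope_sat_pct_min,
#' sub_r2, seal_r2, n, mean_temp_c, rate_mg_min, flagged`.
#'
#' @param slopes A `slope_table`.
#' @param path CSV path.
#' @export
write_slope_table <- function(slopes, path) {
  utils::write.csv(slopes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_slope_table
#' @export
read_slope_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("slope_table", "data.frame")
  out
}

#' Background (blank) respiration at a given time
#'
#' Blank runs before and after the animal trial estimate microbial background
#' uptake. The background applying at any time during the trial is the linear
#' time-interpolation between the two blank rates -- but only when at least
#' one blank exceeds the detection threshold; otherwise the background is
#' taken as zero (no detectable background, so animal rates are not adjusted).
#' Missing blanks give zero with a warning.
#'
#' @param pre_rate,post_rate Blank uptake rates, mg O2 min^-1 (`NA` if the
#'   blank is missing).
#' @param at_time Time at which the background is needed (same units as
#'   `pre_time`/`post_time`; any numeric or POSIXct scale).
#' @param pre_time,post_time Times of the two blank measurements.
#' @param detection_threshold Rates at or below this (both blanks) are treated
#'   as no detectable background (default 0).
#' @return Background uptake rate, mg O2 min^-1.
#' @export
background_rate <- function(pre_rate, post_rate, at_time,
                            pre_time = 0, post_time = 1,
                            detection_threshold = 0) {
  if (is.na(pre_rate) || is.na(post_rate)) {
    warning("missing blank measurement; background treated as 0",
            call. = FALSE)
    return(0)
  }
  if (max(pre_rate, post_rate) <= detection_threshold) return(0)
  at <- as.numeric(at_time); t1 <- as.numeric(pre_time)
  t2 <- as.numeric(post_time)
  if (t2 == t1) return(mean(c(pre_rate, post_rate)))
  frac <- (at - t1) / (t2 - t1)
  pre_rate + frac * (post_rate - pre_rate)
}
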