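#' Dense prediction grid for a fitted thermal-performance curve
#'
#' @param fit A `tpc_fit` (or anything [evaluate_model()] accepts together
#'   with `coefficients`).
#' @param domain Evaluation interval in degrees C. Defaults to the span of
#'   test temperatures used in the metabolic trials, 7.8--30.1 degrees C;
#'   predictions are never extrapolated beyond it unless asked.
#' @param step Grid spacing in degrees C (default 0.01; reported optima are
#'   rounded to 0.1).
#' @param coefficients Optional coefficients when `fit` is a bare model form.
#' @return Data frame with columns `temp_c` and `predicted`.
#' @export
predict_curve <- function(fit, domain = c(7.8, 30.1), step = 0.01,
                          coefficients = NULL) {
  stopifnot_scalar_number(step, "step", positive = TRUE)
  if (length(domain) != 2L || domain[2] <= domain[1]) {
    stop("`domain` must be an increasing pair of temperatures", call. = FALSE)
  }
  X <- seq(domain[1], domain[2], by = step)
  if (X[length(X)] < domain[2]) X <- c(X, domain[2])
  data.frame(temp_c = X, predicted = evaluate_model(fit, coefficients, X))
}

#' Locate the thermal optimum on a prediction grid
#'
#' Argmax of the predicted response; exact ties are broken toward the lowest
#' temperature. An all-equal grid returns the domain lower bound with
#' `tie = TRUE`.
#'
#' @param grid Data frame from [predict_curve()].
#' @return List with `topt` (degrees C, at grid resolution), `peak_value`,
#'   and `tie`.
#' @export
find_topt <- function(grid) {
  if (!nrow(grid)) stop("empty prediction grid", call. = FALSE)
  peak <- max(grid$predicted)
  i <- which(grid$predicted == peak)[1L]
  list(topt = grid$temp_c[i], peak_value = peak,
       tie = all(grid$predicted == peak) && nrow(grid) > 1L)
}

#' Thermal-optimum breadth: the Topt90 / Topt80 range
#'
#' The maximal contiguous temperature interval containing the peak over which
#' the predicted response stays at or above `fraction` of its peak value,
#' clipped to the evaluation domain. If the threshold set is disconnected
#' (possible for wiggly forms), the component containing the peak is reported
#' and the others are flagged via the `"n_other_components"` attribute.
#'
#' @param grid Data frame from [predict_curve()].
#' @param fraction Fraction of the peak to maintain, in (0, 1]; 0.90 gives the
#'   Topt90 range, 0.80 the Topt80 range.
#' @return Numeric `c(lower, upper)` in degrees C at grid resolution, with
#'   attribute `n_other_components`.
#' @export
topt_range <- function(grid, fraction = 0.90) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  pk <- find_topt(grid)
  ok <- grid$predicted >= fraction * pk$peak_value
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  i_peak <- which(grid$temp_c == pk$topt)[1L]
  in_run <- true_runs[starts[true_runs] <= i_peak & ends[true_runs] >= i_peak]
  out <- c(grid$temp_c[starts[in_run]], grid$temp_c[ends[in_run]])
  attr(out, "n_other_components") <- length(true_runs) - 1L
  out
}

#' Predicted response at a temperature as a percent of peak
#'
#' @param grid Data frame from [predict_curve()].
#' @param X Temperature (degrees C) within the grid domain.
#' @return Percent of peak (0--100 scale), unrounded; round to integer for
#'   reporting.
#' @export
percent_of_peak <- function(grid, X) {
  if (X < min(grid$temp_c) || X > max(grid$temp_c)) {
    stop("`X` outside the prediction grid", call. = FALSE)
  }
  pk <- find_topt(grid)
  if (pk$peak_value <= 0) stop("non-positive peak value", call. = FALSE)
  pred <- stats::approx(grid$temp_c, grid$predicted, xout = X)$y
  100 * pred / pk$peak_value
}

#' Summarize thermal optimum and optimum breadth for a fitted curve
#'
#' Builds the dense prediction grid, finds the peak, and reports the Topt90
#' and Topt80 breadths, all rounded to 0.1 degrees C as is conventional for
#' these quantities (the grid itself is computed at `step`).
#'
#' @inheritParams predict_curve
#' @param variable Label for the summarized variable (e.g. "AS").
#' @param fractions Peak fractions defining the breadth intervals.
#' @return A list of class `topt_summary`: `variable`, `topt`, `peak_value`,
#'   `ranges` (one `c(lower, upper)` per fraction, named e.g. `topt90`),
#'   `domain`, and unrounded values in `raw`.
#' @export
topt_summary <- function(fit, variable = "AS", domain = c(7.8, 30.1),
                         step = 0.01, fractions = c(0.90, 0.80),
                         coefficients = NULL) {
  grid <- predict_curve(fit, domain = domain, step = step,
                        coefficients = coefficients)
  pk <- find_topt(grid)
  ranges <- lapply(fractions, function(f) topt_range(grid, f))
  names(ranges) <- sprintf("topt%02d", round(100 * fractions))
  structure(
    list(
      variable = variable,
      topt = round(pk$topt, 1),
      peak_value = pk$peak_value,
      ranges = lapply(ranges, function(r) {
        out <- round(as.numeric(r), 1)
        attr(out, "n_other_components") <- attr(r, "n_other_components")
        out
      }),
      domain = domain,
      raw = list(topt = pk$topt, ranges = ranges)
    ),
    class = "topt_summary"
  )
}

#' @export
print.topt_summary <- function(x, ...) {
  cat(sprintf("<topt_summary %s>  Topt = %.1f C, peak = %.4g\n",
              x$variable, x$topt, x$peak_value))
  for (nm in names(x$ranges)) {
    cat(sprintf("  %s range: %.1f - %.1f C\n", nm,
                x$ranges[[nm]][1], x$ranges[[nm]][2]))
  }
  invisible(x)
}
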