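# Pick the R-squared column an estimator filters on. Bare tables with a
# single `r2` column (e.g. hand-built fixtures) are accepted as-is.
filter_r2 <- function(s, r2_scope = c("seal", "sub_window")) {
  r2_scope <- match.arg(r2_scope)
  col <- if (r2_scope == "seal") "seal_r2" else "sub_r2"
  if (col %in% names(s)) return(s[[col]])
  if ("r2" %in% names(s)) return(s$r2)
  stop(sprintf("no '%s' or 'r2' column in slope table", col), call. = FALSE)
}

#' Resting metabolic rate from overnight slope measurements
#'
#' Pools all overnight slope measurements passing the R-squared filter
#' (`> r2_min`, strictly; negative-uptake flagged sub-windows are also
#' removed), takes the lower `lower_fraction` quantile of the retained rates
#' (linear-interpolation quantile, R type 7), and returns the arithmetic mean
#' of all retained rates at or below that quantile. The lower-decile averaging
#' rejects slope measurements inflated by spontaneous activity, leaving the
#' resting rate.
#'
#' @param slopes A `slope_table` (rows with `phase == "overnight"` are used)
#'   or any data frame with `rate_mg_min`, an R-squared column, and
#'   optionally `flagged`.
#' @param r2_min R-squared threshold (exclusive).
#' @param lower_fraction Quantile defining the "lower" pool (default 0.10).
#' @param r2_scope Which coefficient of determination the filter tests:
#'   `"seal"` (default; the regression over the whole trimmed seal) or
#'   `"sub_window"` (the sub-window's own regression). See
#'   [estimate_slopes()] for why seal scope is the default.
#' @return List with `rate` (mg O2 min^-1), `n_retained` (slopes passing the
#'   filter), and `n_used` (slopes entering the mean).
#' @export
estimate_rmr <- function(slopes, r2_min = 0.90, lower_fraction = 0.10,
                         r2_scope = c("seal", "sub_window")) {
  s <- slopes
  if ("phase" %in% names(s)) {
    s <- s[is.na(s$phase) | s$phase == "overnight", , drop = FALSE]
  }
  r2 <- filter_r2(s, r2_scope)
  keep <- r2 > r2_min & !is.na(r2)
  if ("flagged" %in% names(s)) keep <- keep & !s$flagged
  rates <- s$rate_mg_min[keep]
  if (!length(rates)) {
    stop("trial unusable: no overnight slopes passed the filter",
         call. = FALSE)
  }
  q <- stats::quantile(rates, probs = lower_fraction, type = 7, names = FALSE)
  used <- rates[rates <= q]
  list(rate = mean(used), n_retained = length(rates), n_used = length(used))
}

#' Maximum metabolic rate from chase-protocol slope measurements
#'
#' The highest retained rate among chase-phase slope measurements passing the
#' R-squared filter.
#'
#' @inheritParams estimate_rmr
#' @return List with `rate` (mg O2 min^-1) and `n_retained`.
#' @export
estimate_mmr <- function(slopes, r2_min = 0.90,
                         r2_scope = c("seal", "sub_window")) {
  s <- slopes
  if ("phase" %in% names(s)) {
    s <- s[is.na(s$phase) | s$phase == "chase", , drop = FALSE]
  }
  r2 <- filter_r2(s, r2_scope)
  keep <- r2 > r2_min & !is.na(r2)
  if ("flagged" %in% names(s)) keep <- keep & !s$flagged
  rates <- s$rate_mg_min[keep]
  if (!length(rates)) stop("no valid MMR", call. = FALSE)
  list(rate = max(rates), n_retained = length(rates))
}

#' Absolute and factorial aerobic scope
#'
#' `as_abs = mmr - rmr` (the absolute capacity for aerobic work beyond
#' maintenance) and `fas = mmr / rmr` (the factorial scope). Both identities
#' hold exactly by construction. Vectorized.
#'
#' @param rmr,mmr Resting and maximum metabolic rates, mg O2 min^-1.
#' @return List with `as_abs` and `fas`.
#' @export
compute_scopes <- function(rmr, mmr) {
  if (any(rmr <= 0)) stop("rmr must be positive", call. = FALSE)
  list(as_abs = mmr - rmr, fas = mmr / rmr)
}

#' Process one trial's trace into a per-animal metabolic record
#'
#' Full single-trial chain: segment the trace, estimate sub-window slopes,
#' collapse to RMR (overnight, lower-decile mean) and MMR (chase, maximum),
#' and derive the scopes.
#'
#' @param trace An `oxygen_trace`.
#' @param metadata One-row data frame (or list) with at least `trial_id`,
#'   `population`, `year`, `test_temp_c`, `chamber_volume_ml`, `dry_mass_g`,
#'   `lrr_flag`.
#' @param trim_seconds,min_points Passed to [segment_trace()].
#' @param r2_min,lower_fraction,r2_scope Passed to the rate estimators.
#' @param pressure_kpa Passed to the slope conversion.
#' @param n_sub_overnight,n_sub_chase Passed to [estimate_slopes()].
#' @return One-row data frame (a `metabolic_record`): `trial_id`,
#'   `population`, `year`, `test_temp_c`, `dry_mass_g`, `rmr`, `mmr`, `as`,
#'   `fas`, `n_rmr_slopes`, `n_mmr_slopes`, `lrr_flag`.
#' @export
process_trial <- function(trace, metadata, trim_seconds = 60, min_points = 6,
                          r2_min = 0.90, lower_fraction = 0.10,
                          r2_scope = c("seal", "sub_window"),
                          pressure_kpa = 101.325,
                          n_sub_overnight = 2, n_sub_chase = 5) {
  windows <- segment_trace(trace, trim_seconds = trim_seconds,
                           min_points = min_points)
  slopes <- estimate_slopes(
    windows, volume_l = metadata$chamber_volume_ml / 1000,
    pressure_kpa = pressure_kpa,
    n_sub_overnight = n_sub_overnight, n_sub_chase = n_sub_chase
  )
  rmr <- estimate_rmr(slopes, r2_min = r2_min,
                      lower_fraction = lower_fraction, r2_scope = r2_scope)
  mmr <- estimate_mmr(slopes, r2_min = r2_min, r2_scope = r2_scope)
  scopes <- compute_scopes(rmr$rate, mmr$rate)
  data.frame(
    trial_id = metadata$trial_id, population = metadata$population,
    year = metadata$year, test_temp_c = metadata$test_temp_c,
    dry_mass_g = metadata$dry_mass_g,
    rmr = rmr$rate, mmr = mmr$rate,
    as = scopes$as_abs, fas = scopes$fas,
    n_rmr_slopes = rmr$n_retained, n_mmr_slopes = mmr$n_retained,
    lrr_flag = metadata$lrr_flag
  )
}

#' Write / read per-animal metabolic records
#'
#' Mirrors the supplementary-spreadsheet layout: `trial_id, population, year,
#' test_temp_c, dry_mass_g, rmr, mmr, as, fas, lrr_flag` (plus slope counts).
#'
#' @param records Metabolic records data frame.
#' @param path CSV path.
#' @export
write_metabolic_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metabolic_records
#' @export
read_metabolic_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Allometric-coefficient sensitivity scan
#'
#' Mass effects on nymph metabolism are unquantified, so the thermal-optimum
#' conclusions are screened for sensitivity to the allometric exponent: for
#' each exponent `b` in `b_grid`, RMR and MMR are rescaled to `rate / mass^b`,
#' aerobic scope is recomputed, the scope-vs-temperature response is refit
#' with the model catalog, and the Topt breadth is recorded. A response whose
#' optimum range barely moves across the grid is mass-insensitive.
#'
#' @param records Metabolic records (one row per animal) with `test_temp_c`,
#'   `rmr`, `mmr`, `dry_mass_g`.
#' @param b_grid Allometric exponents to scan.
#' @param fraction Peak fraction defining the reported breadth (0.90).
#' @param domain,step Prediction-grid controls (see [predict_curve()]).
#' @param catalog,n_restarts,seed Passed to [fit_tpc()].
#' @return Data frame: `b`, `model`, `topt`, `lower`, `upper`, `width`; the
#'   spread of each column across `b` measures the drift.
#' @export
allometric_scan <- function(records, b_grid = seq(0, 1, by = 0.05),
                            fraction = 0.90, domain = c(7.8, 30.1),
                            step = 0.01, catalog = model_catalog(),
                            n_restarts = 5, seed = 1) {
  ok <- is.finite(records$dry_mass_g)
  if (any(!ok)) {
    warning(sprintf("%d record(s) without dry mass excluded", sum(!ok)),
            call. = FALSE)
    records <- records[ok, , drop = FALSE]
  }
  rows <- lapply(b_grid, function(b) {
    scale <- records$dry_mass_g^b
    as_adj <- (records$mmr - records$rmr) / scale
    fit <- fit_tpc(data.frame(X = records$test_temp_c, y = as_adj),
                   catalog = catalog, n_restarts = n_restarts,
                   seed = derive_seed(seed, round(100 * b)))
    grid <- predict_curve(fit, domain = domain, step = step)
    rng <- topt_range(grid, fraction)
    pk <- find_topt(grid)
    data.frame(b = b, model = fit$model$name, topt = round(pk$topt, 1),
               lower = round(rng[1], 1), upper = round(rng[2], 1),
               width = round(rng[2] - rng[1], 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summaries of loss-of-righting-response (LRR) flags
#'
#' Counts flagged animals per population, overall and at or above a test
#' temperature threshold. LRR during the chase protocol marks behavioural
#' thermal impairment; measurements from flagged animals are retained in the
#' metabolic dataset.
#'
#' @param records Metabolic records with `population`, `test_temp_c`,
#'   `lrr_flag`.
#' @param temp_threshold Optional threshold; counts flagged records with
#'   `test_temp_c >= temp_threshold`.
#' @return Data frame: `population`, `n`, `n_lrr`, and (when a threshold is
#'   given) `n_lrr_at_or_above`.
#' @export
lrr_summary <- function(records, temp_threshold = NULL) {
  pops <- unique(records$population)
  out <- do.call(rbind, lapply(pops, function(p) {
    r <- records[records$population == p, , drop = FALSE]
    row <- data.frame(population = p, n = nrow(r),
                      n_lrr = sum(r$lrr_flag))
    if (!is.null(temp_threshold)) {
      row$n_lrr_at_or_above <-
        sum(r$lrr_flag & r$test_temp_c >= temp_threshold)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
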