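# Shared fixtures and independent oracles for the test suite.

# Closed-form OLS slope oracle: sum((x - xbar)(y - ybar)) / sum((x - xbar)^2).
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force lower-quantile-mean oracle for the RMR estimator: sort the
# retained rates, take the type-7 quantile, average everything at or below it.
oracle_lower_quantile_mean <- function(rates, fraction = 0.10) {
  q <- as.numeric(quantile(rates, fraction, type = 7))
  mean(sort(rates)[sort(rates) <= q])
}

# Hand-built seal window on an exact line sat = 100 + slope * t(min), at 1 Hz.
make_line_window <- function(slope_per_min = -0.5, minutes = 7, temp = 15,
                             phase = "overnight", noise = 0, seed = 1) {
  t_sec <- 0:(minutes * 60)
  sat <- 100 + slope_per_min * t_sec / 60
  if (noise > 0) {
    set.seed(seed)
    sat <- sat + rnorm(length(sat), 0, noise)
  }
  w <- data.frame(
    timestamp = as.POSIXct("2020-08-20 20:00:00", tz = "UTC") + t_sec,
    do_saturation_pct = sat,
    temp_c = temp,
    phase = if (phase == "chase") "chase_seal" else "seal"
  )
  attr(w, "phase") <- phase
  attr(w, "window_index") <- 1L
  attr(w, "trial_id") <- "fixture"
  class(w) <- c("seal_window", "data.frame")
  w
}

# Minimal slope table for estimator tests (single r2 column is accepted).
make_slope_table <- function(rates, r2 = 1, phase = "overnight") {
  data.frame(
    trial_id = "fixture", phase = phase,
    window_index = seq_along(rates), sub_index = 1L,
    slope_sat_pct_min = -rates, r2 = rep_len(r2, length(rates)),
    n = 30L, mean_temp_c = 15, rate_mg_min = rates,
    flagged = FALSE
  )
}

# Fake fitted object exposing just what select_model() consumes.
make_fake_fit <- function(aic, k, name = paste0("m", k)) {
  structure(list(model = list(name = name, k = k), aic = aic),
            class = "tpc_fit")
}

varney_truth <- function() salmonfly_models()$varney
hebgen_truth <- function() salmonfly_models()$hebgen
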