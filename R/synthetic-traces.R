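#' Ground truth for one synthetic respirometry trial
#'
#' Bundles the quantities the trace generator treats as true: the resting and
#' maximum oxygen-uptake rates, the test temperature, the respirometer water
#' volume, the animal's dry mass, the per-sample measurement noise, and the
#' expected rate of spontaneous overnight activity bursts. Defaults mirror the
#' study conditions: chamber volumes of 129--137 ml and nymph dry masses of
#' 0.034--0.311 g.
#'
#' @param rmr_true Resting oxygen uptake, mg O2 min^-1.
#' @param mmr_true Maximum oxygen uptake, mg O2 min^-1 (must exceed `rmr_true`).
#' @param test_temp Test temperature, degrees C.
#' @param chamber_volume Respirometer water volume, litres.
#' @param dry_mass Nymph dry mass, grams.
#' @param noise_sd Gaussian measurement noise per sample, %-saturation.
#' @param activity_burst_rate Expected spontaneous bursts per hour overnight.
#' @return List of class `trial_truth`.
#' @export
trial_truth <- function(rmr_true, mmr_true, test_temp,
                        chamber_volume = 0.133, dry_mass = 0.14,
                        noise_sd = 0.05, activity_burst_rate = 0.5) {
  stopifnot_scalar_number(rmr_true, "rmr_true", positive = TRUE)
  stopifnot_scalar_number(mmr_true, "mmr_true", positive = TRUE)
  if (mmr_true <= rmr_true) stop("mmr_true must exceed rmr_true", call. = FALSE)
  stopifnot_scalar_number(test_temp, "test_temp")
  stopifnot_scalar_number(chamber_volume, "chamber_volume", positive = TRUE)
  stopifnot_scalar_number(dry_mass, "dry_mass", positive = TRUE)
  if (noise_sd < 0 || activity_burst_rate < 0) {
    stop("noise_sd and activity_burst_rate must be non-negative", call. = FALSE)
  }
  structure(
    list(rmr_true = rmr_true, mmr_true = mmr_true, test_temp = test_temp,
         chamber_volume = chamber_volume, dry_mass = dry_mass,
         noise_sd = noise_sd, activity_burst_rate = activity_burst_rate),
    class = "trial_truth"
  )
}

#' Intermittent-flow respirometry protocol parameters
#'
#' Defaults follow the measurement design: 15-minute seals alternating with
#' 3-minute flushes from 7 p.m. to 9 a.m. (~46 seals overnight), then a
#' 36-minute chase protocol spanning two full flush/seal cycles; the seal
#' duration is chosen so dissolved oxygen never falls below 90% saturation.
#'
#' @param seal_minutes,flush_minutes Phase durations, minutes.
#' @param overnight_start,overnight_end Clock times "HH:MM" bounding the
#'   overnight recording.
#' @param chase_minutes Total chase protocol duration, minutes.
#' @param sample_interval Optode sampling interval, seconds (continuous
#'   recording; 1 s default).
#' @param do_floor Saturation the protocol is designed not to cross, %.
#' @return List of class `resp_protocol`.
#' @export
resp_protocol <- function(seal_minutes = 15, flush_minutes = 3,
                          overnight_start = "19:00", overnight_end = "09:00",
                          chase_minutes = 36, sample_interval = 1,
                          do_floor = 90) {
  stopifnot_scalar_number(seal_minutes, "seal_minutes", positive = TRUE)
  stopifnot_scalar_number(flush_minutes, "flush_minutes", positive = TRUE)
  stopifnot_scalar_number(sample_interval, "sample_interval", positive = TRUE)
  stopifnot_scalar_number(chase_minutes, "chase_minutes", positive = TRUE)
  start_min <- clock_to_minutes(overnight_start)
  end_min <- clock_to_minutes(overnight_end)
  overnight_minutes <- (end_min - start_min) %% (24 * 60)
  if (overnight_minutes == 0) overnight_minutes <- 24 * 60
  structure(
    list(seal_minutes = seal_minutes, flush_minutes = flush_minutes,
         overnight_start = overnight_start, overnight_end = overnight_end,
         overnight_minutes = overnight_minutes, chase_minutes = chase_minutes,
         sample_interval = sample_interval, do_floor = do_floor),
    class = "resp_protocol"
  )
}

#' Generate a synthetic intermittent-flow respirometry trace
#'
#' Builds one trial's oxygen trace: alternating flush/seal cycles overnight
#' followed by the chase protocol's two flush/seal cycles. Within each seal
#' the saturation declines linearly at the slope implied by the current true
#' uptake rate through the inverse of the saturation-to-mass conversion
#' ([saturation_to_mass_rate()]), so a noiseless trace round-trips exactly
#' through the analysis chain. Flushes ramp the saturation back to 100%.
#' Overnight uptake sits at `rmr_true`, transiently elevated by Poisson-placed
#' activity bursts (multiplicative 1.5--3x RMR for 1--5 minutes, capped at
#' `mmr_true`); chase-phase uptake is `mmr_true`. Gaussian noise of sd
#' `noise_sd` is added per sample and the result clamped to
#' \[0, 100 + 3 * noise_sd\].
#'
#' @param truth A [trial_truth()].
#' @param protocol A [resp_protocol()].
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param trial_id Identifier attached to the trace.
#' @param start Timestamp of the first sample (the evening of the trial).
#' @return An `oxygen_trace` data frame: `timestamp`, `do_saturation_pct`,
#'   `temp_c`, `phase` (one of `flush`, `seal`, `chase_flush`, `chase_seal`),
#'   with `trial_id`, `truth`, `protocol` attributes.
#' @export
generate_respirometry_trace <- function(truth, protocol = resp_protocol(),
                                        seed = 1, trial_id = "trial_1",
                                        start = "2020-08-20T19:00:00") {
  stopifnot(inherits(truth, "trial_truth"), inherits(protocol, "resp_protocol"))
  cycle_min <- protocol$seal_minutes + protocol$flush_minutes
  n_seals <- floor(protocol$overnight_minutes / cycle_min)
  if (n_seals < 1) stop("overnight window shorter than one flush/seal cycle",
                        call. = FALSE)
  # worst-case seal decline (sustained maximum uptake) must not empty the chamber
  worst <- -mass_rate_to_sat_slope(truth$mmr_true, truth$test_temp,
                                   truth$chamber_volume) * protocol$seal_minutes
  if (worst >= 100) {
    stop("seal duration would drive saturation below 0 at mmr_true",
         call. = FALSE)
  }
  n_chase_cycles <- max(1L, round(protocol$chase_minutes / cycle_min))

  dt <- protocol$sample_interval
  phase_plan <- data.frame(
    phase = c(rep(c("flush", "seal"), n_seals),
              rep(c("chase_flush", "chase_seal"), n_chase_cycles)),
    minutes = c(rep(c(protocol$flush_minutes, protocol$seal_minutes), n_seals),
                rep(c(protocol$flush_minutes, protocol$seal_minutes),
                    n_chase_cycles))
  )
  n_per_phase <- as.integer(round(phase_plan$minutes * 60 / dt))
  phase <- rep(phase_plan$phase, n_per_phase)
  n <- length(phase)
  t_sec <- (seq_len(n) - 1L) * dt
  overnight_sec <- sum(n_per_phase[seq_len(2L * n_seals)]) * dt

  # per-sample true uptake rate (mg/min)
  rate <- rep(truth$rmr_true, n)
  rate[phase %in% c("chase_flush", "chase_seal")] <- truth$mmr_true

  noise <- numeric(n)
  with_seed(seed, {
    if (truth$activity_burst_rate > 0) {
      n_bursts <- stats::rpois(1, truth$activity_burst_rate *
                                 overnight_sec / 3600)
      if (n_bursts > 0) {
        b_start <- stats::runif(n_bursts, 0, overnight_sec)
        b_dur <- stats::runif(n_bursts, 1, 5) * 60
        b_mult <- stats::runif(n_bursts, 1.5, 3)
        for (i in seq_len(n_bursts)) {
          sel <- t_sec >= b_start[i] & t_sec < b_start[i] + b_dur[i] &
            t_sec < overnight_sec
          rate[sel] <- pmin(pmax(rate[sel], b_mult[i] * truth$rmr_true),
                            truth$mmr_true)
        }
      }
    }
    if (truth$noise_sd > 0) noise <- stats::rnorm(n, 0, truth$noise_sd)
  })

  # integrate saturation: linear decline within seals, linear recovery to 100%
  # during flushes
  slope_per_sec <- mass_rate_to_sat_slope(rate, truth$test_temp,
                                          truth$chamber_volume) / 60
  sat <- numeric(n)
  boundaries <- c(0L, cumsum(n_per_phase))
  current <- 100
  for (p in seq_len(nrow(phase_plan))) {
    idx <- (boundaries[p] + 1L):boundaries[p + 1L]
    if (phase_plan$phase[p] %in% c("seal", "chase_seal")) {
      sat[idx] <- current + cumsum(slope_per_sec[idx] * dt)
      current <- sat[idx[length(idx)]]
    } else {
      sat[idx] <- current + (100 - current) *
        seq_along(idx) / length(idx)
      current <- 100
    }
  }
  if (min(sat) < protocol$do_floor) {
    warning(sprintf(
      "saturation fell to %.1f%%, below the protocol design floor of %g%%",
      min(sat), protocol$do_floor), call. = FALSE)
  }
  sat <- pmin(pmax(sat + noise, 0), 100 + 3 * truth$noise_sd)

  out <- data.frame(
    timestamp = parse_iso8601(start) + t_sec,
    do_saturation_pct = sat,
    temp_c = rep(truth$test_temp, n),
    phase = phase
  )
  attr(out, "trial_id") <- trial_id
  attr(out, "truth") <- truth
  attr(out, "protocol") <- protocol
  class(out) <- c("oxygen_trace", "data.frame")
  out
}

#' Read / write respirometry trace CSVs
#'
#' Trace CSVs have columns `timestamp_iso8601, do_saturation_pct, temp_c,
#' phase` with phase drawn from `flush`, `seal`, `chase_flush`, `chase_seal`.
#'
#' @param path CSV path.
#' @param trial_id Identifier attached on read.
#' @return An `oxygen_trace` data frame.
#' @export
read_oxygen_trace <- function(path, trial_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_oxygen_trace(parse_iso8601(raw$timestamp_iso8601),
                  raw$do_saturation_pct, raw$temp_c, raw$phase,
                  trial_id = trial_id)
}

#' @rdname read_oxygen_trace
#' @param trace An `oxygen_trace`.
#' @export
write_oxygen_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(timestamp_iso8601 = format_iso8601(trace$timestamp),
               do_saturation_pct = trace$do_saturation_pct,
               temp_c = trace$temp_c, phase = trace$phase),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

phase_vocabulary <- c("flush", "seal", "chase_flush", "chase_seal")

as_oxygen_trace <- function(timestamp, do_saturation_pct, temp_c, phase,
                            trial_id = NULL) {
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(do_saturation_pct))) {
    stop("saturation values must be finite", call. = FALSE)
  }
  bad <- setdiff(unique(phase), phase_vocabulary)
  if (length(bad)) {
    stop(sprintf("unknown phase label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(timestamp = timestamp,
                    do_saturation_pct = do_saturation_pct,
                    temp_c = temp_c, phase = phase)
  attr(out, "trial_id") <- trial_id
  class(out) <- c("oxygen_trace", "data.frame")
  out
}
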