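#' Simulate observations of one metabolic variable along a temperature grid
#'
#' Draws `y = curve(temp) + N(0, sd)` for a single thermal-performance curve;
#' the light-weight simulator used for curve-recovery studies.
#'
#' @param model Catalog form name or `tpc_model_spec`.
#' @param coefficients Named coefficients of the generating curve.
#' @param temps Test temperatures, degrees C.
#' @param sd Residual standard deviation (same units as the response).
#' @param seed Integer seed.
#' @return Data frame with `X` (temperature) and `y`, ready for [fit_tpc()].
#' @export
simulate_tpc_observations <- function(model, coefficients, temps, sd, seed = 1) {
  mu <- evaluate_model(model, coefficients, temps)
  y <- if (sd > 0) {
    mu + with_seed(seed, stats::rnorm(length(temps), 0, sd))
  } else mu
  data.frame(X = temps, y = y)
}

#' Generate a synthetic cohort of trial ground truths and metadata
#'
#' Builds the per-animal ground truth for a cohort of respirometry trials:
#' each trial gets exactly one test temperature (one nymph per temperature, as
#' in the measurement design), and its true resting and maximum rates are the
#' population truth curves evaluated at that temperature plus Gaussian
#' between-animal scatter with the curve's residual standard error. Draws that
#' violate `mmr_true > rmr_true > 0` are redrawn (bounded), so the invariant
#' holds in every cohort. Chamber volumes are drawn uniformly on 129--137 ml
#' and dry masses on 0.034--0.311 g, the observed ranges.
#'
#' @param temp_grid Test temperatures, degrees C (default ~1-degree increments
#'   across the tested span 7.8--30.1).
#' @param populations Population truth set: a named list like
#'   [salmonfly_models()] (entries `rmr` and `mmr` are used; set `rse = 0`
#'   for scatter-free cohorts).
#' @param n_per_population Trials per population; defaults to
#'   `length(temp_grid)`, recycling the grid when larger.
#' @param seed Integer seed.
#' @param noise_sd,activity_burst_rate Passed to each [trial_truth()].
#' @param year Cohort year label.
#' @return List with `truths` (named list of [trial_truth()] per trial) and
#'   `metadata` (data frame: `trial_id`, `population`, `year`, `test_temp_c`,
#'   `chamber_volume_ml`, `dry_mass_g`, `lrr_flag`).
#' @export
generate_cohort <- function(temp_grid = seq(7.8, 30.1, by = 1),
                            populations = salmonfly_models(),
                            n_per_population = NULL, seed = 1,
                            noise_sd = 0.05, activity_burst_rate = 0.5,
                            year = 2020L) {
  if (!length(temp_grid)) stop("`temp_grid` must not be empty", call. = FALSE)
  truths <- list()
  meta <- list()
  for (ip in seq_along(populations)) {
    pop <- names(populations)[ip]
    pm <- populations[[pop]]
    n <- if (is.null(n_per_population)) length(temp_grid) else n_per_population
    temps <- rep_len(temp_grid, n)
    mu_rmr <- evaluate_model(pm$rmr$model, pm$rmr$coefficients, temps)
    mu_mmr <- evaluate_model(pm$mmr$model, pm$mmr$coefficients, temps)
    draws <- with_seed(derive_seed(seed, ip), {
      rmr <- mu_rmr + stats::rnorm(n, 0, pm$rmr$rse)
      mmr <- mu_mmr + stats::rnorm(n, 0, pm$mmr$rse)
      for (iter in seq_len(100)) {
        bad <- !(mmr > rmr & rmr > 0)
        if (!any(bad)) break
        rmr[bad] <- mu_rmr[bad] + stats::rnorm(sum(bad), 0, pm$rmr$rse)
        mmr[bad] <- mu_mmr[bad] + stats::rnorm(sum(bad), 0, pm$mmr$rse)
      }
      # final guard for pathological truth curves
      rmr <- pmax(rmr, 1e-5)
      mmr <- pmax(mmr, rmr * 1.05)
      list(rmr = rmr, mmr = mmr,
           vol = stats::runif(n, 0.129, 0.137),
           mass = stats::runif(n, 0.034, 0.311))
    })
    ids <- sprintf("%s_%d_%02d", pop, year, seq_len(n))
    for (i in seq_len(n)) {
      truths[[ids[i]]] <- trial_truth(
        rmr_true = draws$rmr[i], mmr_true = draws$mmr[i],
        test_temp = temps[i], chamber_volume = draws$vol[i],
        dry_mass = draws$mass[i], noise_sd = noise_sd,
        activity_burst_rate = activity_burst_rate
      )
    }
    meta[[pop]] <- data.frame(
      trial_id = ids, population = pop, year = year, test_temp_c = temps,
      chamber_volume_ml = draws$vol * 1000, dry_mass_g = draws$mass,
      lrr_flag = FALSE
    )
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(truths = truths, metadata = metadata)
}

#' Write cohort trial metadata to CSV
#'
#' Columns: `trial_id, population, year, test_temp_c, chamber_volume_ml,
#' dry_mass_g, lrr_flag`.
#'
#' @param metadata Metadata data frame from [generate_cohort()].
#' @param path CSV path.
#' @export
write_trial_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_metadata
#' @export
read_trial_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
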