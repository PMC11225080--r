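#' Bundled fitted metabolic models for two Madison River salmonfly populations
#'
#' Best-fit thermal-performance models for resting metabolic rate (RMR),
#' maximum metabolic rate (MMR), absolute aerobic scope (AS) and factorial
#' aerobic scope (FAS) of giant salmonfly (*Pteronarcys californica*) nymphs
#' from the Varney (warmer, more variable) and Hebgen (cooler, dam-stabilized)
#' sites on the Madison River, MT. Rates are in mg O2 min^-1, FAS is unitless,
#' and the temperature covariate is degrees C. These fits are shipped as
#' reference coefficients: they drive [reference_scope_report()], act as the
#' default ground-truth curves of [generate_cohort()], and carry the residual
#' standard errors used to draw realistic between-animal scatter.
#'
#' @return Nested list `models[[population]][[variable]]`, each entry a list
#'   with `model` (catalog form name), `coefficients`, and `rse`.
#' @seealso [model_catalog()], [reference_scope_report()]
#' @export
salmonfly_models <- function() {
  list(
    varney = list(
      rmr = list(
        model = "linear",
        coefficients = list(a = -0.0001697, b = 0.0001064),
        rse = 0.00053
      ),
      mmr = list(
        model = "log_poly",
        coefficients = list(a = -0.179513194, b = -0.009180676,
                            c = 0.077496005, d = 0.233963066),
        rse = 0.00109
      ),
      as = list(
        model = "log_poly",
        coefficients = list(a = 0.035180899, b = -0.003037786,
                            c = 0.003954095, d = -0.109130843),
        rse = 0.00083
      ),
      fas = list(
        model = "log_poly",
        coefficients = list(a = -270.5207792, b = -12.35124834,
                            c = 108.9238294, d = 388.232928),
        rse = 0.8106
      )
    ),
    hebgen = list(
      rmr = list(
        model = "poly_x15_x2",
        coefficients = list(a = 0.001060934, b = -0.0000371, c = 0.0000105),
        rse = 0.00060
      ),
      mmr = list(
        model = "double_exponential",
        coefficients = list(rho = 0.149283294, tmax = 31.49806582,
                            delta = 6.697500268),
        rse = 0.00129
      ),
      as = list(
        model = "x2logx_x3",
        coefficients = list(a = -0.000219669, b = 0.0000134, c = -0.00000149),
        rse = 0.00105
      ),
      fas = list(
        model = "quadratic",
        coefficients = list(a = -1.142947682, b = 0.539868645, c = -0.0159921),
        rse = 0.6946
      )
    )
  )
}

#' August habitat temperature extremes at the two Madison River sites
#'
#' Observed August maximum hourly temperature and August mean 7DADMax (mean of
#' the 7-day sliding averages of daily maxima) from the field logger record at
#' the Varney and Hebgen sites, 2020 and 2021. Bundled as reference inputs for
#' thermal-safety-margin arithmetic when the raw logger series is not
#' available.
#'
#' @return Data frame with columns `site`, `year`, `august_max_c`,
#'   `august_mean_7dadmax_c`.
#' @export
august_extremes <- function() {
  data.frame(
    site = rep(c("varney", "hebgen"), each = 2),
    year = c(2020L, 2021L, 2020L, 2021L),
    august_max_c = c(21.9, 21.8, 19.9, 18.7),
    august_mean_7dadmax_c = c(19.4, 18.6, 17.9, 17.7)
  )
}

#' Evaluate the bundled population models and derive every reported quantity
#'
#' Evaluates all eight bundled fits ([salmonfly_models()]; two populations by
#' four metabolic variables) on a dense temperature grid and derives the full
#' set of summary quantities: predictions at 8 and 28 degrees C, the
#' fold-change of RMR between those temperatures, peak value and Topt for the
#' hump-shaped variables, Topt90/Topt80 breadths, percent of peak at 28
#' degrees C, and thermal safety margins for each site and year using the
#' bundled August extremes ([august_extremes()]) against the population's AS
#' Topt90 upper limit.
#'
#' Reporting conventions: temperatures to 0.1 degrees C, fold-changes and FAS
#' to one decimal, percents of peak to the nearest integer, TSMs to 0.1
#' degrees C; rates are left unrounded.
#'
#' @param domain Evaluation interval, degrees C.
#' @param step Grid spacing, degrees C.
#' @return Nested list of class `scope_report`: per population, per variable
#'   `at8`, `at28`, and (for MMR/AS/FAS) `topt`, `peak`, `topt90`, `topt80`,
#'   `pct_peak_at28`; RMR additionally `fold_8_28`; plus `tsm`, a data frame
#'   of TSM_Max and TSM_7DADMax per site and year.
#' @export
reference_scope_report <- function(domain = c(7.8, 30.1), step = 0.01) {
  models <- salmonfly_models()
  out <- list()
  for (pop in names(models)) {
    pop_out <- list()
    for (var in names(models[[pop]])) {
      m <- models[[pop]][[var]]
      grid <- predict_curve(m$model, domain = domain, step = step,
                            coefficients = m$coefficients)
      entry <- list(
        model = m$model,
        at8 = evaluate_model(m$model, m$coefficients, 8),
        at28 = evaluate_model(m$model, m$coefficients, 28)
      )
      if (var == "rmr") {
        entry$fold_8_28 <- round(entry$at28 / entry$at8, 1)
      } else {
        pk <- find_topt(grid)
        entry$topt <- round(pk$topt, 1)
        entry$peak <- pk$peak_value
        entry$topt90 <- round(as.numeric(topt_range(grid, 0.90)), 1)
        entry$topt80 <- round(as.numeric(topt_range(grid, 0.80)), 1)
        entry$pct_peak_at28 <- round(percent_of_peak(grid, 28))
      }
      pop_out[[var]] <- entry
    }
    out[[pop]] <- pop_out
  }

  aug <- august_extremes()
  tsm <- do.call(rbind, lapply(seq_len(nrow(aug)), function(i) {
    upper <- out[[aug$site[i]]]$as$topt90[2]
    cbind(
      aug[i, , drop = FALSE],
      topt90_upper_c = upper,
      as.data.frame(thermal_safety_margin(
        upper, aug$august_max_c[i], aug$august_mean_7dadmax_c[i]
      )[c("tsm_max", "tsm_7dadmax")])
    )
  }))
  rownames(tsm) <- NULL
  out$tsm <- tsm
  structure(out, class = c("scope_report", "list"))
}

#' @export
print.scope_report <- function(x, ...) {
  for (pop in setdiff(names(x), "tsm")) {
    cat(sprintf("== %s ==\n", pop))
    for (var in names(x[[pop]])) {
      e <- x[[pop]][[var]]
      cat(sprintf("  %-4s %-18s at8 = %.3g  at28 = %.3g", toupper(var),
                  paste0("[", e$model, "]"), e$at8, e$at28))
      if (!is.null(e$topt)) {
        cat(sprintf("  peak = %.3g @ %.1f C  Topt90 = [%.1f, %.1f]",
                    e$peak, e$topt, e$topt90[1], e$topt90[2]))
      }
      cat("\n")
    }
  }
  cat("== thermal safety margins ==\n")
  print(x$tsm, row.names = FALSE)
  invisible(x)
}
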