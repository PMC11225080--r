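#' Cancellation-aware double-exponential thermal performance form
#'
#' Evaluates `exp(rho * X) - exp(rho * tmax - (tmax - X) / delta)`, the
#' rise-and-crash curve whose two exponential terms nearly cancel close to the
#' peak (they agree to ~4 significant figures there while their difference
#' carries the signal). The difference is therefore computed as
#' `exp(s2) * expm1(s1 - s2)`, which preserves full relative precision in the
#' small difference instead of subtracting two large, nearly equal numbers.
#'
#' @param X Temperature, degrees C.
#' @param rho Exponential rate of the rising limb (per degree C).
#' @param tmax Temperature at which the curve crosses zero on the way down.
#' @param delta Width parameter of the crash (degrees C).
#' @return Predicted response, same length as `X`.
#' @export
tpc_double_exp <- function(X, rho, tmax, delta) {
  s1 <- rho * X
  s2 <- rho * tmax - (tmax - X) / delta
  exp(s2) * expm1(s1 - s2)
}

tpc_log_poly <- function(X, a, b, c, d) {
  lx <- log(X)
  a + b * lx^2 + c * lx + d * lx / X
}

#' Catalog of candidate thermal-performance model forms
#'
#' Returns the candidate model forms fit to each metabolic variable as a
#' function of temperature `X`. All logarithms are natural logarithms. Each
#' entry carries the symbolic right-hand side used by the least-squares
#' fitter, the parameter names, the parameter count `k`, a prediction
#' function, and a data-driven starting-value rule. The forms that are linear
#' in their coefficients get exact ordinary-least-squares starting values via
#' their basis expansion; the double-exponential form uses a heuristic start
#' (log-slope of the rising limb, peak position from the data).
#'
#' @return A named list of `tpc_model_spec` objects, in catalog order (used as
#'   the final tie-break in [select_model()]).
#' @examples
#' names(model_catalog())
#' @export
model_catalog <- function() {
  specs <- list(
    tpc_model_spec(
      name = "linear", rhs = "a + b * X", params = c("a", "b"),
      fun = function(X, p) p[["a"]] + p[["b"]] * X,
      basis = function(X) cbind(1, X)
    ),
    tpc_model_spec(
      name = "quadratic", rhs = "a + b * X + c * X^2",
      params = c("a", "b", "c"),
      fun = function(X, p) p[["a"]] + p[["b"]] * X + p[["c"]] * X^2,
      basis = function(X) cbind(1, X, X^2)
    ),
    tpc_model_spec(
      name = "poly_x15_x2", rhs = "a + b * X^1.5 + c * X^2",
      params = c("a", "b", "c"),
      fun = function(X, p) p[["a"]] + p[["b"]] * X^1.5 + p[["c"]] * X^2,
      basis = function(X) cbind(1, X^1.5, X^2)
    ),
    tpc_model_spec(
      name = "x2logx_x3", rhs = "a + b * X^2 * log(X) + c * X^3",
      params = c("a", "b", "c"),
      fun = function(X, p) p[["a"]] + p[["b"]] * X^2 * log(X) + p[["c"]] * X^3,
      basis = function(X) cbind(1, X^2 * log(X), X^3)
    ),
    tpc_model_spec(
      name = "log_poly",
      rhs = "a + b * log(X)^2 + c * log(X) + d * log(X)/X",
      params = c("a", "b", "c", "d"),
      fun = function(X, p) tpc_log_poly(X, p[["a"]], p[["b"]], p[["c"]], p[["d"]]),
      basis = function(X) cbind(1, log(X)^2, log(X), log(X) / X)
    ),
    tpc_model_spec(
      name = "double_exponential",
      rhs = "tpc_double_exp(X, rho, tmax, delta)",
      params = c("rho", "tmax", "delta"),
      fun = function(X, p) tpc_double_exp(X, p[["rho"]], p[["tmax"]], p[["delta"]]),
      basis = NULL,
      starts = function(X, y) {
        pos <- y > 0 & X <= X[which.max(y)]
        rho <- 0.1
        if (sum(pos) >= 3) {
          b <- stats::coef(stats::lm(log(y[pos]) ~ X[pos]))[2]
          if (is.finite(b) && b > 0) rho <- as.numeric(b)
        }
        c(rho = rho, tmax = max(X) + 2, delta = diff(range(X)) / 4)
      }
    )
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

tpc_model_spec <- function(name, rhs, params, fun, basis = NULL, starts = NULL) {
  structure(
    list(name = name, rhs = rhs, params = params, k = length(params),
         fun = fun, basis = basis, starts = starts),
    class = "tpc_model_spec"
  )
}

#' @export
print.tpc_model_spec <- function(x, ...) {
  cat(sprintf("<tpc model '%s'>  y ~ %s   (k = %d)\n", x$name, x$rhs, x$k))
  invisible(x)
}

resolve_spec <- function(model) {
  if (inherits(model, "tpc_model_spec")) return(model)
  if (is.character(model) && length(model) == 1L) {
    cat_ <- model_catalog()
    if (!model %in% names(cat_)) {
      stop(sprintf("unknown model form '%s'", model), call. = FALSE)
    }
    return(cat_[[model]])
  }
  stop("`model` must be a tpc_model_spec or a catalog name", call. = FALSE)
}

#' Evaluate a thermal-performance model at given temperatures
#'
#' @param model A `tpc_model_spec`, a catalog name (see [model_catalog()]),
#'   or a `tpc_fit` (in which case its own coefficients are used).
#' @param coefficients Named numeric vector or list supplying every parameter
#'   of the form. Ignored when `model` is a `tpc_fit` and omitted.
#' @param X Temperatures (degrees C) at which to predict.
#' @return Predicted response values.
#' @examples
#' evaluate_model("linear", c(a = 0, b = 1), X = 5)
#' @export
evaluate_model <- function(model, coefficients = NULL, X) {
  if (inherits(model, "tpc_fit")) {
    if (is.null(coefficients)) coefficients <- model$coefficients
    model <- model$model
  }
  spec <- resolve_spec(model)
  coefficients <- as.list(coefficients)
  missing <- setdiff(spec$params, names(coefficients))
  if (length(missing)) {
    stop(sprintf("missing parameter(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  spec$fun(X, coefficients)
}

default_starts <- function(spec, X, y) {
  if (!is.null(spec$basis)) {
    # Linear-in-coefficients: exact OLS start via the basis expansion.
    fit <- stats::lm.fit(spec$basis(X), y)
    st <- stats::coef(fit)
    names(st) <- spec$params
    return(st)
  }
  spec$starts(X, y)
}

# Gaussian-likelihood AIC counting the error variance as a parameter; matches
# stats::AIC() on lm/nls objects. Only AIC differences are ever interpreted.
gaussian_aic <- function(rss, n, k) {
  n * log(2 * pi * rss / n) + n + 2 * (k + 1)
}

#' Fit one thermal-performance model by damped least squares
#'
#' Minimizes the residual sum of squares of `y` against the model form with
#' Levenberg--Marquardt iteration ([minpack.lm::nlsLM()]), from data-driven
#' default starting values plus `n_restarts` multiplicatively jittered
#' restarts (each parameter scaled by an independent U\[0.5, 2\] draw) to
#' reduce the risk of local minima. The best converged fit by RSS is kept.
#' Fits that overflow or fail to converge are discarded silently as long as at
#' least one start converges.
#'
#' @param model A `tpc_model_spec` or catalog name.
#' @param data Data frame (or list) with numeric columns `X` (temperature,
#'   degrees C) and `y` (response).
#' @param starts Optional named starting values; defaults to the catalog rule.
#' @param n_restarts Number of jittered restarts on top of the default start.
#' @param seed Seed for the restart jitter.
#' @return A `tpc_fit`: the model spec, fitted `coefficients`, `rss`,
#'   residual standard error `rse = sqrt(rss/df)`, `df = n - k`, `aic`
#'   (Gaussian form, error variance counted as a parameter), `adj_r2` from
#'   [fit_quality()], and `n`.
#' @seealso [fit_tpc()] to fit the whole catalog and select by AIC.
#' @export
fit_model <- function(model, data, starts = NULL, n_restarts = 10, seed = 1) {
  spec <- resolve_spec(model)
  X <- as.numeric(data$X)
  y <- as.numeric(data$y)
  if (length(X) != length(y) || anyNA(X) || anyNA(y)) {
    stop("`data` must supply complete numeric X and y of equal length",
         call. = FALSE)
  }
  n <- length(y)
  if (n <= spec$k) {
    stop(sprintf("n = %d observations cannot identify %d parameters", n, spec$k),
         call. = FALSE)
  }
  base_start <- if (is.null(starts)) default_starts(spec, X, y) else unlist(starts)
  if (!all(spec$params %in% names(base_start))) {
    stop("`starts` must name every model parameter", call. = FALSE)
  }
  base_start <- base_start[spec$params]

  start_sets <- list(base_start)
  if (n_restarts > 0) {
    jitter <- with_seed(seed, matrix(
      stats::runif(n_restarts * spec$k, 0.5, 2), nrow = n_restarts
    ))
    for (i in seq_len(n_restarts)) {
      start_sets[[i + 1L]] <- base_start * jitter[i, ]
    }
  }

  form <- stats::as.formula(paste("y ~", spec$rhs),
                            env = asNamespace("thermoscope"))
  df_fit <- data.frame(X = X, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)

  best <- NULL
  for (st in start_sets) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = df_fit, start = as.list(st), control = ctrl
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, coef = stats::coef(fit))
    }
  }
  if (is.null(best)) {
    stop(sprintf("model '%s' did not converge from any start", spec$name),
         call. = FALSE)
  }

  coefs <- as.list(best$coef)
  fitted <- spec$fun(X, coefs)
  k <- spec$k
  df <- n - k
  rss <- best$rss
  adj <- tryCatch(suppressWarnings(fit_quality(y, fitted)),
                  error = function(e) NA_real_)
  structure(
    list(
      model = spec,
      coefficients = coefs,
      rss = rss,
      rse = sqrt(rss / df),
      df = df,
      n = n,
      aic = gaussian_aic(rss, n, k),
      adj_r2 = adj
    ),
    class = "tpc_fit"
  )
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit '%s'>  n = %d, df = %d\n", x$model$name, x$n, x$df))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients),
                    unlist(x$coefficients)), collapse = ", "), "\n")
  cat(sprintf("  RSS = %.6g, RSE = %.6g, AIC = %.3f, adj r2 = %.3f\n",
              x$rss, x$rse, x$aic, x$adj_r2))
  invisible(x)
}

#' Select the best-supported model with a 2-unit parsimony rule
#'
#' Among fits whose AIC lies within `delta` units of the minimum AIC, the fit
#' with the fewest parameters is chosen; ties on parameter count are broken by
#' lower AIC, then by catalog order. Selection depends only on AIC
#' differences, never on their absolute level.
#'
#' @param fits A list of `tpc_fit` objects.
#' @param delta Width of the competitive AIC window (default 2 units).
#' @return The selected `tpc_fit`.
#' @export
select_model <- function(fits, delta = 2) {
  if (!length(fits)) stop("`fits` is empty", call. = FALSE)
  aic <- vapply(fits, `[[`, 0, "aic")
  k <- vapply(fits, function(f) f$model$k, 0)
  competitive <- which(aic <= min(aic) + delta)
  ord <- order(k[competitive], aic[competitive], competitive)
  fits[[competitive[ord[1L]]]]
}

#' Fit-quality statistic: adjusted r-squared of observed on fitted
#'
#' The variance explained by a nonlinear fit is summarized as the adjusted
#' r-squared of the intercept-and-slope linear regression of the observed
#' values on the model's fitted values.
#'
#' @param observed Observed response values.
#' @param fitted Model-fitted values at the same temperatures.
#' @return Adjusted r-squared (scalar).
#' @export
fit_quality <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 3) {
    stop("need >= 3 paired observed/fitted values", call. = FALSE)
  }
  if (stats::var(fitted) == 0) {
    stop("fitted values are constant; fit quality undefined", call. = FALSE)
  }
  summary(stats::lm(observed ~ fitted))$adj.r.squared
}

#' Fit the full catalog and select the best-supported form
#'
#' Fits every form in `catalog` to `(X, y)` and applies [select_model()].
#' Forms that fail to converge are dropped (with a warning naming them); at
#' least one form must survive.
#'
#' @inheritParams fit_model
#' @param catalog List of model specs, by default [model_catalog()].
#' @param delta Parsimony window for [select_model()].
#' @return The selected `tpc_fit`, with the full fit list in attribute
#'   `"all_fits"`.
#' @export
fit_tpc <- function(data, catalog = model_catalog(), delta = 2,
                    n_restarts = 10, seed = 1) {
  fits <- list()
  failed <- character()
  for (spec in catalog) {
    f <- tryCatch(
      fit_model(spec, data, n_restarts = n_restarts,
                seed = derive_seed(seed, spec$k)),
      error = function(e) NULL
    )
    if (is.null(f)) failed <- c(failed, spec$name) else fits[[spec$name]] <- f
  }
  if (length(failed)) {
    warning(sprintf("form(s) failed to converge and were dropped: %s",
                    paste(failed, collapse = ", ")), call. = FALSE)
  }
  if (!length(fits)) stop("no catalog form converged", call. = FALSE)
  best <- select_model(fits, delta = delta)
  attr(best, "all_fits") <- fits
  best
}

#' Serialize a fitted model to JSON (and back)
#'
#' @param fit A `tpc_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `tpc_fit_to_json()`: a JSON string (invisibly, when written to a
#'   file); `tpc_fit_from_json()`: a `tpc_fit`.
#' @export
tpc_fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "tpc_fit"))
  obj <- list(
    model = fit$model$name,
    coefficients = fit$coefficients,
    rss = fit$rss, rse = fit$rse, df = fit$df, n = fit$n,
    aic = fit$aic, adj_r2 = fit$adj_r2
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname tpc_fit_to_json
#' @param json A JSON string or file path produced by [tpc_fit_to_json()].
#' @export
tpc_fit_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(
    list(
      model = resolve_spec(obj$model),
      coefficients = as.list(obj$coefficients),
      rss = obj$rss, rse = obj$rse, df = obj$df, n = obj$n,
      aic = obj$aic, adj_r2 = obj$adj_r2
    ),
    class = "tpc_fit"
  )
}
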