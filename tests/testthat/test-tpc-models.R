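# Model catalog, nonlinear fitting, AIC selection, fit quality.

test_that("catalog carries at least the six required forms, all evaluable", {
  cat_ <- model_catalog()
  expect_gte(length(cat_), 6)
  expect_setequal(
    intersect(names(cat_), c("linear", "quadratic", "poly_x15_x2",
                             "x2logx_x3", "log_poly", "double_exponential")),
    c("linear", "quadratic", "poly_x15_x2", "x2logx_x3", "log_poly",
      "double_exponential")
  )
  # every form finite at 20 C from its data-driven default starts
  X <- seq(8, 30, 1)
  y <- -(X - 18)^2 / 100 + 4 + rnorm(length(X), 0, 0.05)
  for (spec in cat_) {
    st <- thermoscope:::default_starts(spec, X, y)
    expect_true(is.finite(evaluate_model(spec, st, 20)), label = spec$name)
  }
  expect_equal(evaluate_model("linear", c(a = 0, b = 1), 5), 5)
  expect_error(evaluate_model("linear", c(a = 0), 5), "missing parameter")
})

test_that("bundled coefficients reproduce reported point predictions", {
  m <- salmonfly_models()
  expect_equal(evaluate_model(m$varney$rmr$model, m$varney$rmr$coefficients, 8),
               6.81e-4, tolerance = 0.002)
  expect_equal(evaluate_model(m$hebgen$mmr$model, m$hebgen$mmr$coefficients, 8),
               2.03e-3, tolerance = 0.01)
  expect_equal(evaluate_model(m$varney$fas$model, m$varney$fas$coefficients, 8),
               3.5, tolerance = 0.01)
})

test_that("linear fits match the closed-form normal-equations oracle", {
  set.seed(31)
  X <- runif(30, 8, 30)
  y <- 2e-4 + 1.1e-4 * X + rnorm(30, 0, 5e-5)
  fit <- fit_model("linear", data.frame(X = X, y = y), seed = 1)
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(fit$coefficients$a, beta[1], tolerance = 1e-8)
  expect_equal(fit$coefficients$b, beta[2], tolerance = 1e-8)
  # Gaussian AIC convention matches stats::AIC on the same model
  expect_equal(fit$aic, AIC(lm(y ~ X)), tolerance = 1e-8)
  expect_equal(fit$df, fit$n - 2)
  expect_equal(fit$rse, sqrt(fit$rss / fit$df))
})

test_that("noiseless data from a catalog form is recovered exactly", {
  temps <- seq(7.8, 30.1, length.out = 40)
  truth <- varney_truth()$as
  d <- simulate_tpc_observations(truth$model, truth$coefficients, temps,
                                 sd = 0, seed = 1)
  fit <- suppressWarnings(fit_model("log_poly", d, seed = 1))
  expect_lt(fit$rss, 1e-18)
  for (p in names(truth$coefficients)) {
    expect_equal(fit$coefficients[[p]], truth$coefficients[[p]],
                 tolerance = 1e-6)
  }
})

test_that("refitting from the fitted coefficients is a fixed point", {
  set.seed(4)
  temps <- seq(8, 30, 1)
  d <- data.frame(X = temps,
                  y = 1 + 0.4 * temps - 0.01 * temps^2 + rnorm(23, 0, 0.1))
  f1 <- fit_model("quadratic", d, seed = 1)
  f2 <- fit_model("quadratic", d, starts = unlist(f1$coefficients),
                  n_restarts = 0, seed = 1)
  expect_equal(unlist(f1$coefficients), unlist(f2$coefficients),
               tolerance = 1e-8)
})

test_that("selection applies the 2-unit parsimony rule", {
  f_single <- make_fake_fit(100, 3)
  expect_identical(select_model(list(f_single)), f_single)
  # within 2 units the simpler model wins
  picked <- select_model(list(make_fake_fit(100.0, 4), make_fake_fit(101.5, 2)))
  expect_equal(picked$model$k, 2)
  # outside the window the better-AIC model wins
  picked2 <- select_model(list(make_fake_fit(100.0, 4), make_fake_fit(103.0, 2)))
  expect_equal(picked2$model$k, 4)
  expect_error(select_model(list()), "empty")
})

test_that("selection is invariant to a constant AIC shift", {
  fits <- list(make_fake_fit(100.0, 4, "a"), make_fake_fit(101.5, 2, "b"),
               make_fake_fit(104.0, 3, "c"))
  shifted <- lapply(fits, function(f) {
    f$aic <- f$aic + 1000
    f
  })
  expect_identical(select_model(fits)$model$name,
                   select_model(shifted)$model$name)
})

test_that("fit quality is 1 for perfect fits and ~0 for unrelated fits", {
  obs <- rnorm(30)
  expect_equal(suppressWarnings(fit_quality(obs, obs)), 1)
  set.seed(55)
  vals <- replicate(500, fit_quality(rnorm(30), rnorm(30)))
  expect_lt(abs(mean(vals)), 0.02)
  expect_error(fit_quality(rnorm(10), rep(1, 10)), "constant")
})

test_that("double-exponential evaluation survives near-peak cancellation", {
  co <- hebgen_truth()$mmr$coefficients
  x <- 24.8
  s1 <- co$rho * x
  s2 <- co$rho * co$tmax - (co$tmax - x) / co$delta
  # the two terms agree to ~4 significant figures near the peak
  expect_equal(exp(s1), 40.54, tolerance = 0.001)
  expect_equal(exp(s2), 40.53, tolerance = 0.001)
  got <- tpc_double_exp(x, co$rho, co$tmax, co$delta)
  naive <- exp(s1) - exp(s2)
  expect_equal(got, naive, tolerance = 1e-9)
  expect_equal(got, 7.1e-3, tolerance = 0.01)
})

test_that("refitted residual error matches the generating noise level", {
  truth <- varney_truth()$as
  temps <- seq(7.8, 30.1, length.out = 44)
  rses <- vapply(1:40, function(s) {
    d <- simulate_tpc_observations(truth$model, truth$coefficients, temps,
                                   sd = 0.00083, seed = s)
    fit_model("log_poly", d, n_restarts = 3, seed = s)$rse
  }, 0)
  expect_lt(abs(mean(rses) - 0.00083) / 0.00083, 0.25)
})

test_that("catalog fitting drops non-convergent forms and selects sensibly", {
  truth <- hebgen_truth()$fas
  temps <- seq(8, 30, 1)
  d <- simulate_tpc_observations(truth$model, truth$coefficients, temps,
                                 sd = 0.3, seed = 6)
  fit <- suppressWarnings(fit_tpc(d, seed = 6))
  expect_s3_class(fit, "tpc_fit")
  all_fits <- attr(fit, "all_fits")
  expect_gte(length(all_fits), 3)
  aics <- vapply(all_fits, `[[`, 0, "aic")
  expect_lte(fit$aic, min(aics) + 2)
  expect_error(fit_model("linear", data.frame(X = 1:2, y = 1:2)),
               "cannot identify")
})

test_that("fits serialize to JSON and back", {
  set.seed(9)
  d <- data.frame(X = seq(8, 30, 1),
                  y = 2 + 0.1 * seq(8, 30, 1) + rnorm(23, 0, 0.2))
  fit <- fit_model("linear", d, seed = 1)
  js <- tpc_fit_to_json(fit)
  back <- tpc_fit_from_json(js)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic)
  expect_identical(back$model$name, "linear")
  expect_equal(evaluate_model(back, X = 15), evaluate_model(fit, X = 15))
})
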