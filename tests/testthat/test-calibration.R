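test_that("CVRMSE evaluates its defining cases and invariances", {
  expect_equal(cvrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cvrmse(c(2, 2, 2, 2), c(1, 1, 1, 1)), 50)
  a <- c(1.2, 2.1, 0.7, 1.9); b <- c(1.0, 2.4, 0.9, 1.7)
  expect_equal(cvrmse(10 * a, 10 * b), cvrmse(a, b))
  expect_error(cvrmse(c(1, 2), c(1, 2, 3)), "length")
  expect_error(cvrmse(c(1, -1), c(0, 0)), "zero")
})

glucose_setup <- function(seed = 42, noise_cv = 0.05) {
  model <- glucose_reference_model()
  des <- experiment_design("glucose", seed = seed, noise_cv = noise_cv)
  dat <- generate_experiment(model, des)
  list(model = model, design = des, data = dat,
       init = default_initial_state(des, model))
}

test_that("a perfect fit has zero cost and the penalty counts active modes", {
  s <- glucose_setup(noise_cv = 0)
  truth <- list(mu_max = s$model$params$mu_max, alpha = s$model$params$alpha)
  expect_equal(calibration_cost(truth, s$model, s$data, s$init, lambda = 0), 0,
               tolerance = 1e-4)
  c0 <- calibration_cost(truth, s$model, s$data, s$init, lambda = 2)
  expect_equal(c0, 2 * sum(truth$mu_max > 1e-4), tolerance = 1e-4)
  # an inactive reaction (mu below threshold) does not change the penalty
  mu2 <- c(truth$mu_max, 1e-6)
  model5 <- build_dmm(glucose_macro_reactions()[c("e2", "e5", "e6", "e9", "e1")],
                      kinetic_params(mu_max = mu2, K = 9e-3, kd = 8.33e-4,
                                     alpha = 6.15e-4))
  c5 <- calibration_cost(list(mu_max = mu2, alpha = truth$alpha),
                         model5, s$data, s$init, lambda = 2)
  expect_equal(c5, c0, tolerance = 1e-3)
})

test_that("cost is invariant to replicate and variable ordering", {
  s <- glucose_setup()
  pars <- list(mu_max = s$model$params$mu_max, alpha = s$model$params$alpha)
  c1 <- calibration_cost(pars, s$model, s$data, s$init)
  shuffled <- s$data
  shuffled$observations <- rev(shuffled$observations)
  shuffled$observations <- lapply(shuffled$observations,
                                  function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  c2 <- calibration_cost(pars, s$model, shuffled, s$init)
  expect_equal(c1, c2)
})

test_that("calibration recovers the generating rate constants", {
  s <- glucose_setup(seed = 77)
  res <- suppressWarnings(calibrate(s$model, s$data, s$init,
                                    n_starts = 2, maxit = 80))
  rel <- abs(res$estimates$mu_max - s$model$params$mu_max) / s$model$params$mu_max
  expect_true(all(rel < 0.15))
  expect_true(res$convergence)
  # optimizer sanity: calibrated CVRMSE no worse than the truth's own CVRMSE
  expect_true(all(res$cvrmse < 100))
})

test_that("noiseless data give near-exact parameter recovery", {
  s <- glucose_setup(seed = 5, noise_cv = 0)
  res <- suppressWarnings(calibrate(s$model, s$data, s$init,
                                    n_starts = 2, maxit = 120))
  rel <- abs(res$estimates$mu_max - s$model$params$mu_max) / s$model$params$mu_max
  expect_true(all(rel < 0.01))
  expect_equal(res$estimates$alpha, 6.15e-4, tolerance = 0.01)
})

test_that("fitting proceeds when a variable is missing", {
  s <- glucose_setup(seed = 9)
  s$data$observations$formate <- NULL
  res <- suppressWarnings(calibrate(s$model, s$data, s$init,
                                    n_starts = 1, maxit = 40))
  expect_s3_class(res, "calibration_result")
  expect_false("formate" %in% names(res$cvrmse))
})

test_that("increasing the penalty never increases the active-mode count", {
  s <- glucose_setup(seed = 13)
  n_active <- vapply(c(0, 50, 500), function(lam) {
    res <- suppressWarnings(calibrate(s$model, s$data, s$init, lambda = lam,
                                      n_starts = 1, maxit = 50))
    length(res$active_efms)
  }, 0L)
  expect_true(all(diff(n_active) <= 0))
})

test_that("duplicated macro reactions are flagged as non-identifiable", {
  macros <- glucose_macro_reactions()[c("e2", "e2")]
  macros[[2]]$id <- "e2b"
  model <- build_dmm(macros, kinetic_params(mu_max = c(0.05, 0.05), K = 9e-3,
                                            kd = 8.33e-4, alpha = 6.15e-4))
  des <- experiment_design("glucose", seed = 31)
  dat <- generate_experiment(model, des)
  expect_warning(
    parameter_correlations(model, dat, default_initial_state(des, model)),
    "correlation|identifiab")
})

test_that("cellulose-style fits estimate the initial biomass", {
  macros <- glucose_macro_reactions()[c("e2", "e6")]
  truth <- kinetic_params(mu_max = c(0.05, 0.3), Kc = 2, kd = 8.33e-4)
  model <- build_dmm(macros, truth, substrate_carbon = 24)
  des <- experiment_design("cellulose", seed = 55)
  expect_false(des$observe_od)
  dat <- generate_experiment(model, des)
  expect_false("od" %in% names(dat$observations))
  init <- c(substrate = initial_substrate_molar(des), ammonium = 0.03)
  res <- suppressWarnings(calibrate(model, dat, init = as.list(init),
                                    n_starts = 2, maxit = 60))
  expect_true(res$estimates$B0 > 0)
  rel <- abs(res$estimates$mu_max - truth$mu_max) / truth$mu_max
  expect_true(all(rel < 0.5)) # B0/mu trade-off limits precision without OD
})

test_that("time series containers validate their schema", {
  expect_error(time_series_data(c(0), list()), "increasing")
  expect_error(time_series_data(c(0, 5), list(foo = matrix(1, 1, 2))), "unknown")
  expect_error(time_series_data(c(0, 5), list(substrate = matrix(1, 1, 3))),
               "align")
  d <- time_series_data(c(0, 5), list(substrate = matrix(1, 2, 2)))
  expect_s3_class(d, "time_series_data")
})
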