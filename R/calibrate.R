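#' Coefficient of variation of the RMSE
#'
#' `100 * RMSE / mean(observed)`, in percent. Scale-invariant: rescaling
#' both vectors by a common factor leaves the value unchanged.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 1),
#'   `NA`s in `observed` are dropped pairwise.
#' @return CVRMSE in percent.
#' @export
#' @examples
#' cvrmse(c(2, 2, 2, 2), c(1, 1, 1, 1)) # 50
cvrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  keep <- !is.na(observed) & !is.na(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (!length(observed)) stop("no paired observations")
  mu <- mean(observed)
  if (abs(mu) < 1e-300) stop("mean of observations is zero; CVRMSE undefined")
  100 * sqrt(mean((observed - predicted)^2)) / abs(mu)
}

#' Batch-culture time-series data container
#'
#' @param times Sampling times (h), increasing, length >= 2.
#' @param observations Named list of replicate x time matrices (one row per
#'   replicate), in mol/L except `od` (unitless). Allowed variables:
#'   substrate, acetate, succinate, formate, ammonia, od.
#' @param substrate Substrate name the data refer to.
#' @return A `time_series_data`.
#' @export
time_series_data <- function(times, observations, substrate = "glucose") {
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("need >= 2 strictly increasing time points")
  }
  allowed <- c("substrate", "acetate", "succinate", "formate", "ammonia", "od")
  bad <- setdiff(names(observations), allowed)
  if (length(bad)) stop(sprintf("unknown variable(s): %s", paste(bad, collapse = ", ")))
  for (v in names(observations)) {
    observations[[v]] <- as.matrix(observations[[v]])
    if (ncol(observations[[v]]) != length(times)) {
      stop(sprintf("variable '%s': columns must align with times", v))
    }
  }
  structure(list(times = times, observations = observations,
                 substrate = substrate),
            class = "time_series_data")
}

#' @export
print.time_series_data <- function(x, ...) {
  cat(sprintf("time_series_data: %s, %d time points (%s h), variables: %s\n",
              x$substrate, length(x$times),
              paste(x$times, collapse = ", "),
              paste(names(x$observations), collapse = ", ")))
  invisible(x)
}

# map model states to data variables
variable_prediction <- function(traj, variable) {
  switch(variable,
         substrate = traj$substrate,
         acetate = traj$acetate,
         succinate = traj$succinate,
         formate = traj$formate,
         ammonia = traj$ammonium,
         od = traj$od,
         stop(sprintf("no model output for variable '%s'", variable)))
}

build_model_with <- function(model, mu_max = NULL, alpha = NULL) {
  p <- model$params
  if (!is.null(mu_max)) p$mu_max <- mu_max
  if (!is.null(alpha)) p$alpha <- alpha
  model$params <- p
  # stoichiometry does not depend on the kinetic parameters
  model
}

# per-variable measurement variance from replicate scatter (pooled over
# time points); falls back to a fraction of the signal scale when the data
# carry no replication
variable_variances <- function(data) {
  vapply(names(data$observations), function(v) {
    m <- data$observations[[v]]
    if (nrow(m) >= 2L) {
      dev <- sweep(m, 2, colMeans(m, na.rm = TRUE))
      pooled <- sum(dev^2, na.rm = TRUE) /
        max(sum(!is.na(dev)) - sum(colSums(!is.na(m)) > 0), 1L)
      if (is.finite(pooled) && pooled > 0) return(pooled)
    }
    scale <- mean(abs(m), na.rm = TRUE)
    max((0.05 * scale)^2, 1e-20)
  }, 0)
}

#' Calibration cost: penalized weighted least squares
#'
#' Negative Gaussian log-likelihood (up to a constant) under independent
#' errors with per-variable constant variance: the weighted residual sum of
#' squares `sum_v RSS_v / (2 sigma_v^2)` with `sigma_v^2` estimated from
#' the replicate scatter of each variable, plus an EFM-count penalty
#' `lambda * #(mu_max > activity_threshold)` discouraging models that keep
#' many macroscopic reactions active. Simulation failures return a
#' large-but-finite cost so quasi-Newton optimizers can recover.
#'
#' @param params Named list/vector with `mu_max` (vector), optional `alpha`,
#'   optional `B0`.
#' @param model A `dynamic_model` template.
#' @param data A `time_series_data`.
#' @param init Named initial state (its `biomass` entry is overridden by
#'   `params$B0` when present).
#' @param lambda Penalty weight (default 0).
#' @param activity_threshold mu_max above which a reaction counts as active
#'   (default 1e-4 /h).
#' @return Scalar cost.
#' @export
calibration_cost <- function(params, model, data, init, lambda = 0,
                             activity_threshold = 1e-4) {
  mu <- params$mu_max
  # line searches can wander to absurd rate constants; refuse to simulate
  # far outside the biologically meaningful range instead of fighting the
  # integrator there
  if (any(!is.finite(mu)) || any(mu > 50)) {
    return(1e8 + sum(pmin(mu, 1e6), na.rm = TRUE))
  }
  model2 <- build_model_with(model, mu_max = mu, alpha = params$alpha)
  if (!is.null(params$B0)) init[["biomass"]] <- params$B0
  t0 <- data$times
  sim_times <- if (t0[1] > 0) c(0, t0) else t0
  traj <- tryCatch(
    simulate_dmm(model2, init, sim_times, rtol = 1e-6, atol = 1e-10),
    error = function(e) NULL)
  if (is.null(traj)) {
    warning("simulation failed during cost evaluation; returning large cost")
    return(1e8)
  }
  traj <- traj[match(t0, traj$time), , drop = FALSE]
  vars <- attr(data, "variances")
  if (is.null(vars)) vars <- variable_variances(data)
  nll <- 0
  for (v in names(data$observations)) {
    obs <- data$observations[[v]]
    pred <- variable_prediction(traj, v)
    resid <- sweep(obs, 2, pred)
    rss <- sum(resid^2, na.rm = TRUE)
    nll <- nll + rss / (2 * vars[[v]])
  }
  nll + lambda * sum(mu > activity_threshold)
}

# relative utilization of each macro reaction inferred from the net change
# of the observed products over the experiment (non-negative least squares
# against the reaction coefficients); returns NULL when no product variable
# is observed
pathway_utilization_guess <- function(model, data) {
  state_of <- c(acetate = "acetate", succinate = "succinate",
                formate = "formate", ammonia = "ammonium", od = "biomass")
  vars <- intersect(names(data$observations), names(state_of))
  rows <- intersect(state_of[vars], rownames(model$stoich))
  if (!length(rows)) return(NULL)
  A <- model$stoich[rows, , drop = FALSE]
  dp <- vapply(rows, function(sp) {
    v <- names(state_of)[state_of == sp][1]
    m <- data$observations[[v]]
    d <- mean(m[, ncol(m)], na.rm = TRUE) - mean(m[, 1], na.rm = TRUE)
    if (sp == "biomass") d * 6.15e-4 else d # nominal alpha for the OD guess
  }, 0)
  # per-row normalization so small-magnitude products still inform the fit
  sc <- pmax(abs(dp), 1e-12)
  A <- A / sc; dp <- dp / sc
  u <- tryCatch(drop(solve(crossprod(A) + diag(1e-8, ncol(A)), crossprod(A, dp))),
                error = function(e) NULL)
  if (is.null(u)) return(NULL)
  u <- pmax(u, max(abs(u)) * 1e-3 + 1e-12)
  u / sum(u)
}

unpack_theta <- function(theta, layout) {
  nmu <- layout$n_mu
  out <- list(mu_max = 10^theta[seq_len(nmu)])
  k <- nmu
  if (layout$fit_alpha) { out$alpha <- 10^theta[k + 1]; k <- k + 1 }
  if (layout$fit_B0) out$B0 <- 10^theta[k + 1]
  out
}

#' Calibrate a dynamic metabolic model against time-series data
#'
#' Maximum-likelihood estimation of the per-reaction rate constants (and
#' optionally the OD conversion factor `alpha` and, for particulate
#' substrates without OD data, the initial biomass `B0`) by quasi-Newton
#' (BFGS) minimization of [calibration_cost()] in log10 parameter space,
#' from seeded Latin-hypercube multi-starts over mu_max in [1e-4, 2] /h.
#' The Monod constant `K` and the death rate `kd` are fixed by default
#' (K = 9e-3 M, kd = 8.33e-4 /h) to avoid the well-known practical
#' identifiability problems of Monod kinetics on sparse noisy batch data.
#'
#' @param model A `dynamic_model` template (its `mu_max` entries serve only
#'   to size the parameter vector).
#' @param data A `time_series_data`.
#' @param init Named initial state.
#' @param fit_alpha Estimate `alpha` (default: TRUE when OD is observed).
#' @param fit_B0 Estimate initial biomass (default: TRUE when OD is absent).
#' @param lambda,activity_threshold EFM penalty, as in [calibration_cost()].
#' @param n_starts Number of Latin-hypercube starts (default 20).
#' @param seed RNG seed for the start design (default 20230608).
#' @param maxit BFGS iteration cap per start.
#' @param mu_range log10 search range for mu_max starts.
#' @return A `calibration_result` with `estimates`, `fixed`, `cost`,
#'   `cvrmse` (percent per variable), `active_efms`, `convergence`.
#' @export
calibrate <- function(model, data, init, fit_alpha = "od" %in% names(data$observations),
                      fit_B0 = !("od" %in% names(data$observations)) &&
                               is.null(init[["biomass"]]),
                      lambda = 0, activity_threshold = 1e-4,
                      n_starts = 20, seed = 20230608, maxit = 150,
                      mu_range = c(1e-4, 2)) {
  nmu <- length(model$params$mu_max)
  layout <- list(n_mu = nmu, fit_alpha = fit_alpha, fit_B0 = fit_B0)
  npar <- nmu + fit_alpha + fit_B0
  n_obs <- sum(vapply(data$observations, function(m) sum(!is.na(m)), 0))
  if (n_obs < npar) {
    warning(sprintf("only %d observations for %d free parameters; expect identifiability problems",
                    n_obs, npar))
  }
  if (is.null(init[["biomass"]]) && !fit_B0) stop("init must give biomass unless B0 is estimated")
  if (is.null(init[["biomass"]])) init[["biomass"]] <- 1e-5
  attr(data, "variances") <- variable_variances(data)
  objfun <- function(theta) {
    pars <- unpack_theta(theta, layout)
    calibration_cost(pars, model, data, init, lambda, activity_threshold)
  }
  set.seed(seed)
  H <- lhs::randomLHS(max(n_starts, 1L) + 3L, npar)
  lo <- log10(mu_range[1]); hi <- log10(mu_range[2])
  starts <- matrix(lo + H * (hi - lo), ncol = npar)
  if (fit_alpha) starts[, nmu + 1] <- log10(6.15e-4) + (H[, nmu + 1] - 0.5) * 2
  if (fit_B0) starts[, npar] <- log10(1e-5) + (H[, npar] - 0.5) * 3
  # data-driven candidate starts: pathway-utilization fractions from the
  # observed product increments, combined with a coarse rate-scale grid
  u <- pathway_utilization_guess(model, data)
  if (!is.null(u)) {
    extra <- do.call(rbind, lapply(c(0.05, 0.2, 0.8), function(cc) {
      th <- log10(pmax(cc * u, mu_range[1]))
      c(th, if (fit_alpha) log10(6.15e-4), if (fit_B0) log10(1e-5))
    }))
    starts <- rbind(extra, starts)
  }
  # rank all candidate starts by one cost evaluation; optimize the best few
  vals <- apply(starts, 1, function(th) tryCatch(objfun(th), error = function(e) Inf))
  starts <- starts[order(vals), , drop = FALSE][seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  best <- NULL
  conv <- FALSE; iters <- 0L
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch({
      pre <- stats::optim(starts[k, ], objfun, method = "Nelder-Mead",
                          control = list(maxit = 4L * maxit, reltol = 1e-10))
      stats::optim(pre$par, objfun, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
      iters <- fit$counts[["function"]]
    }
  }
  if (is.null(best)) stop("all optimization starts failed")
  est <- unpack_theta(best$par, layout)
  model_hat <- build_model_with(model, mu_max = est$mu_max, alpha = est$alpha)
  init_hat <- init
  if (!is.null(est$B0)) init_hat[["biomass"]] <- est$B0
  t0 <- data$times
  sim_times <- if (t0[1] > 0) c(0, t0) else t0
  traj <- simulate_dmm(model_hat, init_hat, sim_times)
  traj <- traj[match(t0, traj$time), , drop = FALSE]
  cv <- vapply(names(data$observations), function(v) {
    obs <- data$observations[[v]]
    pred <- matrix(variable_prediction(traj, v), nrow(obs), ncol(obs), byrow = TRUE)
    cvrmse(as.numeric(obs), as.numeric(pred))
  }, 0)
  macro_ids <- vapply(model$macros, function(m) m$id, "")
  structure(list(
    estimates = est,
    fixed = list(K = model$params$K, Kc = model$params$Kc, kd = model$params$kd,
                 alpha = if (fit_alpha) NULL else model$params$alpha),
    cost = best$value,
    cvrmse = cv,
    active_efms = macro_ids[est$mu_max > activity_threshold],
    convergence = conv,
    iterations = iters,
    model = model_hat,
    init = init_hat),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result\n")
  cat("  mu_max:", paste(signif(x$estimates$mu_max, 4), collapse = ", "), "/h\n")
  if (!is.null(x$estimates$alpha)) cat("  alpha:", signif(x$estimates$alpha, 4), "M/OD\n")
  if (!is.null(x$estimates$B0)) cat("  B0:", signif(x$estimates$B0, 4), "M\n")
  cat("  cost:", signif(x$cost, 6), "| converged:", x$convergence, "\n")
  cat("  CVRMSE (%):", paste(sprintf("%s=%.1f", names(x$cvrmse), x$cvrmse), collapse = ", "), "\n")
  cat("  active reactions:", paste(x$active_efms, collapse = ", "), "\n")
  invisible(x)
}

#' Practical-identifiability diagnostics
#'
#' Finite-difference Fisher information of the residual vector at a
#' parameter point, returned as a parameter correlation matrix. Pairwise
#' correlations above `warn_above` trigger a warning — the classic
#' signature of practically non-identifiable Monod parameters.
#'
#' @param model A `dynamic_model`.
#' @param data A `time_series_data`.
#' @param init Initial state.
#' @param params Parameter list (as in [calibration_cost()]) at which to
#'   linearize; defaults to the model's own parameters.
#' @param rel_step Relative finite-difference step.
#' @param warn_above Correlation threshold for the warning.
#' @return Correlation matrix of the estimable parameters.
#' @export
parameter_correlations <- function(model, data, init, params = NULL,
                                   rel_step = 1e-4, warn_above = 0.95) {
  if (is.null(params)) params <- list(mu_max = model$params$mu_max)
  theta <- log10(unlist(params))
  resid_fun <- function(th) {
    pars <- utils::relist(10^th, params)
    m2 <- build_model_with(model, mu_max = pars$mu_max, alpha = pars$alpha)
    if (!is.null(pars$B0)) init[["biomass"]] <- pars$B0
    t0 <- data$times
    sim_times <- if (t0[1] > 0) c(0, t0) else t0
    traj <- simulate_dmm(m2, init, sim_times, rtol = 1e-8)
    traj <- traj[match(t0, traj$time), , drop = FALSE]
    unlist(lapply(names(data$observations), function(v) {
      obs <- data$observations[[v]]
      as.numeric(sweep(obs, 2, variable_prediction(traj, v)))
    }))
  }
  r0 <- resid_fun(theta)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_step * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (resid_fun(tp) - resid_fun(tm)) / (2 * h)
  }
  keep <- !is.na(r0)
  FIM <- crossprod(J[keep, , drop = FALSE])
  Cov <- tryCatch(solve(FIM + diag(1e-12, ncol(FIM))), error = function(e) NULL)
  if (is.null(Cov)) {
    warning("Fisher information is singular; parameters not identifiable")
    return(matrix(NA_real_, length(theta), length(theta)))
  }
  Cor <- stats::cov2cor(Cov)
  dimnames(Cor) <- list(names(theta), names(theta))
  off <- abs(Cor[upper.tri(Cor)])
  if (any(off > warn_above)) {
    warning(sprintf("high parameter correlation (max |r| = %.3f): practical identifiability problem",
                    max(off)))
  }
  Cor
}
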