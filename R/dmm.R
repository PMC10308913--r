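#' Monod reaction rate
#'
#' Saturating kinetics for a soluble substrate:
#' \deqn{\rho = \mu_{max}\,\frac{s}{K + s}\,B}
#' with `s` and `B` in mol/L, `mu_max` in 1/h and the Monod affinity
#' constant `K` in mol/L. At `s = K` the rate is half its maximum.
#'
#' @param s Substrate concentration (M), non-negative.
#' @param B Biomass concentration (M, C-mol basis), non-negative.
#' @param mu_max Rate constant (1/h).
#' @param K Monod constant (M).
#' @return Reaction rate (M/h).
#' @export
monod_rate <- function(s, B, mu_max, K) {
  if (any(c(s, B, mu_max, K) < 0)) stop("monod_rate: negative input")
  mu_max * s / (K + s) * B
}

#' Contois reaction rate
#'
#' Biomass-dependent saturation appropriate for particulate (surface-
#' limited) substrates such as cellulose:
#' \deqn{\rho = \mu_{max}\,\frac{s}{K_c B + s}\,B}
#' The half-saturation point scales with biomass (`s = Kc B`); as `Kc -> 0`
#' the law reduces to first-order-in-B Monod kinetics with `K = 0`.
#'
#' @param s Substrate concentration (M), non-negative.
#' @param B Biomass concentration (M, C-mol basis), non-negative.
#' @param mu_max Rate constant (1/h).
#' @param Kc Dimensionless Contois constant (biomass-relative).
#' @return Reaction rate (M/h).
#' @export
contois_rate <- function(s, B, mu_max, Kc) {
  if (any(c(s, B, mu_max, Kc) < 0)) stop("contois_rate: negative input")
  den <- Kc * B + s
  if (den <= 0) return(0)
  mu_max * s / den * B
}

# the single place where the kinetic interpretation lives: rho_i is the
# SUBSTRATE-CONSUMPTION rate of macro reaction i (the alternative reading,
# biomass-production rate, would divide by f_i here)
reaction_rates <- function(s, B, params) {
  s <- max(s, 0); B <- max(B, 0)
  if (params$kinetics == "monod") {
    vapply(params$mu_max, function(mm) monod_rate(s, B, mm, params$K), 0)
  } else {
    vapply(params$mu_max, function(mm) contois_rate(s, B, mm, params$Kc), 0)
  }
}

#' Kinetic parameter set for a dynamic metabolic model
#'
#' @param mu_max Numeric vector of rate constants (1/h), one per macro
#'   reaction.
#' @param K Monod constant (M) — soluble substrates.
#' @param Kc Contois constant (dimensionless) — particulate substrates.
#'   Exactly one of `K`/`Kc` must be given; it selects the kinetics.
#' @param kd First-order death rate constant (1/h), default 8.33e-4.
#' @param alpha Conversion factor biomass molarity -> optical density
#'   (M/OD), default 6.15e-4.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(mu_max, K = NULL, Kc = NULL, kd = 8.33e-4,
                           alpha = 6.15e-4) {
  if (is.null(K) == is.null(Kc)) stop("give exactly one of K (Monod) or Kc (Contois)")
  if (any(mu_max < 0) || kd < 0 || (!is.null(K) && K < 0) ||
      (!is.null(Kc) && Kc < 0) || alpha <= 0) {
    stop("kinetic parameters must be non-negative (alpha positive)")
  }
  structure(list(mu_max = mu_max, K = K, Kc = Kc, kd = kd, alpha = alpha,
                 kinetics = if (is.null(Kc)) "monod" else "contois"),
            class = "kinetic_params")
}

#' Build a dynamic metabolic model from macroscopic reactions
#'
#' Assembles the batch-fermentation ODE system driven by the macroscopic
#' reactions: with \eqn{\rho_i} the substrate-consumption rate of reaction
#' i (Monod or Contois),
#' \deqn{ds/dt = -\sum_i \rho_i, \qquad
#'   dB/dt = \sum_i f'_i \rho_i - k_d B,}
#' and each tracked product follows its stoichiometric coefficient.
#' `f'_i` is the biomass yield converted from g/mmol substrate to
#' C-mol/mol. The glycogen state is carried in glucose-equivalents (six per
#' table unit). Bookkeeping species (salts, ATP, CoA, protons, PPi) are
#' integrated as cumulative production fluxes, not concentrations — the
#' medium is buffered and they are artifacts of the network reduction.
#'
#' @param macros List of `macro_reaction`s sharing one substrate.
#' @param params A [kinetic_params()] set with `length(mu_max) ==
#'   length(macros)`.
#' @param substrate_carbon Carbon atoms per substrate unit (6 for glucose,
#'   12 cellobiose, 24 cellulose in moles of the native molecule).
#' @param carbon_per_unit Named carbon content per unit of each tracked
#'   species, for carbon bookkeeping; defaults cover the canonical species.
#' @return A `dynamic_model`.
#' @export
build_dmm <- function(macros, params, substrate_carbon = 6,
                      carbon_per_unit = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(params$mu_max) != length(macros)) {
    stop("need one mu_max per macroscopic reaction")
  }
  subs <- unique(vapply(macros, function(m) m$substrate_id, ""))
  if (length(subs) != 1L) stop("macro reactions mix substrates; build one model per substrate")
  species <- Reduce(union, lapply(macros, function(m) names(m$coef)))
  species <- setdiff(species, c("substrate", "biomass",
                                vapply(macros, function(m) m$substrate_id, ""),
                                unlist(lapply(macros, function(m) m$biomass_id))))
  tracked <- setdiff(species, BOOKKEEPING_SPECIES)
  book <- intersect(species, BOOKKEEPING_SPECIES)
  states <- c("substrate", "biomass", tracked)
  nr <- length(macros)
  M <- matrix(0, length(states) + length(book), nr,
              dimnames = list(c(states, if (length(book)) paste0("cum_", book)), NULL))
  f_gmmol <- numeric(nr)
  for (i in seq_len(nr)) {
    m <- macros[[i]]
    coef <- m$coef
    M["substrate", i] <- -1
    bid <- if (!is.null(m$biomass_id) && m$biomass_id %in% names(coef)) m$biomass_id
           else if ("biomass" %in% names(coef)) "biomass" else NULL
    f_gmmol[i] <- if (is.null(bid)) 0 else max(coef[[bid]], 0)
    M["biomass", i] <- f_gmmol[i] * 1000 / biomass_g_per_mol_c
    for (sp in intersect(tracked, names(coef))) {
      M[sp, i] <- coef[[sp]] * (if (sp == "glycogen") 6 else 1)
    }
    for (sp in intersect(book, names(coef))) {
      M[paste0("cum_", sp), i] <- coef[[sp]]
    }
  }
  cpu <- CARBON_PER_UNIT
  if (!is.null(carbon_per_unit)) cpu[names(carbon_per_unit)] <- carbon_per_unit
  carbon <- stats::setNames(numeric(length(states)), states)
  carbon["substrate"] <- substrate_carbon
  carbon["biomass"] <- 1 # C-mol basis
  for (sp in tracked) {
    carbon[sp] <- if (sp == "glycogen") 6 # state is glucose-equivalents
                  else if (sp %in% names(cpu)) cpu[[sp]] else 0
  }
  # CO2 is tracked as cumulative net exchange with the (CO2-saturated)
  # headspace: negative values mean net uptake, so it is exempt from the
  # non-negativity guard
  structure(list(macros = macros, params = params, states = states,
                 bookkeeping = book, stoich = M, f_g_per_mmol = f_gmmol,
                 substrate_id = subs, carbon = carbon,
                 sign_free = intersect(states, "co2")),
            class = "dynamic_model")
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat(sprintf("dynamic_model: %d macroscopic reactions on %s, %s kinetics\n",
              length(x$macros), x$substrate_id, x$params$kinetics))
  cat("states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a dynamic metabolic model
#'
#' Stiff-capable integration (deSolve `lsoda`) of the batch-fermentation
#' ODE at relative tolerance 1e-8. States are guarded against negative
#' excursions: concentrations are clamped at zero inside the right-hand
#' side and an excursion beyond -1e-9 raises an error. Optical density is
#' reported as `B / alpha`.
#'
#' @param model A `dynamic_model`.
#' @param init Named initial state; missing tracked species start at 0.
#'   `substrate` and `biomass` are required (M).
#' @param times Increasing output time grid (h).
#' @param rtol,atol Integration tolerances.
#' @return A `trajectory`: data.frame with `time`, the states, `od`, plus
#'   cumulative bookkeeping fluxes.
#' @export
simulate_dmm <- function(model, init, times, rtol = 1e-8, atol = 1e-12) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  y0 <- stats::setNames(numeric(nrow(model$stoich)), rownames(model$stoich))
  common <- intersect(names(init), names(y0))
  y0[common] <- unlist(init[common])
  if (any(y0 < 0)) stop("negative initial state")
  rhs <- function(t, y, p) {
    rho <- reaction_rates(y[["substrate"]], y[["biomass"]], model$params)
    dy <- drop(model$stoich %*% rho)
    dy["biomass"] <- dy["biomass"] - model$params$kd * max(y[["biomass"]], 0)
    list(dy)
  }
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE solver failed; check parameters/tolerances")
  df <- as.data.frame(out)
  guarded <- setdiff(model$states, model$sign_free)
  worst <- min(as.matrix(df[, guarded]))
  if (worst < -1e-9 * max(1, max(abs(as.matrix(df[, guarded]))))) {
    stop("state excursion below -1e-9 during integration")
  }
  for (sp in guarded) df[[sp]] <- pmax(df[[sp]], 0)
  df$od <- df$biomass / model$params$alpha
  class(df) <- c("trajectory", class(df))
  df
}

#' Total carbon along a trajectory
#'
#' Stoichiometric bookkeeping of carbon: the carbon-weighted sum of all
#' tracked states at each time point. For carbon-closed macroscopic
#' reactions and `kd = 0` this is constant along the trajectory (death
#' removes biomass carbon from the balance).
#'
#' @param traj A `trajectory`.
#' @param model The `dynamic_model` that produced it.
#' @return Numeric vector of total carbon (M of C) per time point.
#' @export
trajectory_carbon <- function(traj, model) {
  tot <- numeric(nrow(traj))
  for (sp in model$states) tot <- tot + model$carbon[[sp]] * traj[[sp]]
  tot
}

#' Net carbon balance of macroscopic reactions
#'
#' Carbon produced minus carbon consumed per unit substrate for each macro
#' reaction, under the model's carbon-per-unit accounting (includes ATP and
#' CoA carbon for completeness when those species are present).
#'
#' @param model A `dynamic_model`.
#' @return Numeric vector, one net carbon per macro reaction (0 = closed).
#' @export
macro_carbon_balance <- function(model) {
  vapply(seq_along(model$macros), function(i) {
    sum(model$carbon[model$states] * model$stoich[model$states, i])
  }, 0)
}
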