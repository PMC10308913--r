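#' Flux balance analysis
#'
#' Maximizes a weighted sum of reaction fluxes subject to the intracellular
#' steady-state constraint `Si v = 0` and the reaction bounds. Alternate
#' optima are possible; any optimal vertex may be returned, but the
#' objective value (and yields derived from it) is unique.
#'
#' @param net A `metabolic_network`.
#' @param objective Reaction id, or named numeric vector of
#'   (reaction id -> weight); defaults to the network objective.
#' @param bounds_override Optional named list/vector of `c(lb, ub)` pairs
#'   (or a single number fixing both bounds) keyed by reaction id.
#' @param extra_eq Optional list with `A` (k x n matrix over reactions) and
#'   `b` adding equality constraints (used internally for yield fixing).
#' @return A `flux_vector`: list with `values` (named fluxes), `objective_value`,
#'   `status` in `optimal|infeasible|unbounded`.
#' @export
fba <- function(net, objective = NULL, bounds_override = NULL, extra_eq = NULL) {
  r <- net$reactions
  if (is.null(objective)) objective <- net$objective
  if (is.null(objective)) stop("no objective given and network has none")
  w <- stats::setNames(numeric(nrow(r)), r$id)
  if (is.character(objective)) {
    missing <- setdiff(objective, r$id)
    if (length(missing)) stop(sprintf("objective reaction(s) not in network: %s",
                                      paste(missing, collapse = ", ")))
    w[objective] <- 1
  } else {
    missing <- setdiff(names(objective), r$id)
    if (length(missing)) stop(sprintf("objective reaction(s) not in network: %s",
                                      paste(missing, collapse = ", ")))
    w[names(objective)] <- objective
  }
  lb <- r$lb; ub <- r$ub
  if (!is.null(bounds_override)) {
    for (id in names(bounds_override)) {
      j <- match(id, r$id)
      if (is.na(j)) stop(sprintf("bounds_override names unknown reaction '%s'", id))
      bv <- bounds_override[[id]]
      if (length(bv) == 1L) bv <- c(bv, bv)
      lb[j] <- bv[1]; ub[j] <- bv[2]
    }
  }
  Si <- stoichiometric_matrix(net, "intracellular")
  Aeq <- Si; beq <- rep(0, nrow(Si))
  if (!is.null(extra_eq)) {
    Aeq <- rbind(Aeq, extra_eq$A)
    beq <- c(beq, extra_eq$b)
  }
  sol <- solve_lp(w, Aeq, beq, lb, ub, maximize = TRUE)
  vals <- if (sol$status == "optimal") {
    v <- sol$x
    v[abs(v) < 1e-9] <- 0
    stats::setNames(v, r$id)
  } else stats::setNames(rep(NA_real_, nrow(r)), r$id)
  structure(list(values = vals, objective_value = sol$objective,
                 status = sol$status),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("flux_vector: status=%s, objective=%s\n", x$status,
              format(x$objective_value)))
  nz <- x$values[!is.na(x$values) & abs(x$values) > 0]
  if (length(nz)) print(round(nz, 6))
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum flux of every reaction while the objective is held at
#' (at least) `fraction` of its optimum.
#'
#' @param net A `metabolic_network`.
#' @param objective As in [fba()].
#' @param fraction Required fraction of the optimal objective (default 1).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(net, objective = NULL, fraction = 1.0) {
  base <- fba(net, objective)
  if (base$status != "optimal") stop("FVA requires an optimal base solution")
  if (is.null(objective)) objective <- net$objective
  r <- net$reactions
  w <- stats::setNames(numeric(nrow(r)), r$id)
  if (is.character(objective)) w[objective] <- 1 else w[names(objective)] <- objective
  Si <- stoichiometric_matrix(net, "intracellular")
  lb <- r$lb; ub <- r$ub
  lo <- hi <- numeric(nrow(r))
  target <- fraction * base$objective_value
  # objective >= target encoded as equality with a surplus variable is
  # avoided: reuse solve_lp with an extra row via big-M free surplus —
  # instead fix the objective exactly at its optimum when fraction == 1.
  for (j in seq_len(nrow(r))) {
    cj <- stats::setNames(numeric(nrow(r)), r$id); cj[j] <- 1
    A <- rbind(Si, w); b <- c(rep(0, nrow(Si)), target)
    smin <- solve_lp(cj, A, b, lb, ub, maximize = FALSE)
    smax <- solve_lp(cj, A, b, lb, ub, maximize = TRUE)
    lo[j] <- smin$objective; hi[j] <- smax$objective
  }
  data.frame(reaction = r$id, min = lo, max = hi, stringsAsFactors = FALSE)
}

#' Essential reactions for an objective
#'
#' A reaction is essential when fixing its flux to zero drops the optimal
#' objective below `viability_fraction` times the wild-type optimum.
#'
#' @param net A `metabolic_network`.
#' @param biomass_id Objective reaction id (defaults to network objective).
#' @param viability_fraction Threshold in (0, 1); default 0.01.
#' @return Character vector of essential reaction ids.
#' @export
essential_reactions <- function(net, biomass_id = NULL, viability_fraction = 0.01) {
  if (is.null(biomass_id)) biomass_id <- net$objective
  wt <- fba(net, biomass_id)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9) {
    stop("wild-type optimum is zero or infeasible; essentiality undefined")
  }
  thr <- viability_fraction * wt$objective_value
  ess <- character()
  for (id in net$reactions$id) {
    if (id == biomass_id) { ess <- c(ess, id); next }
    ko <- fba(net, biomass_id, bounds_override = stats::setNames(list(c(0, 0)), id))
    if (ko$status != "optimal" || ko$objective_value < thr) ess <- c(ess, id)
  }
  ess
}

resolve_exchange <- function(net, id) {
  # id may be a reaction id or an extracellular metabolite id; returns a
  # linear functional over fluxes measuring the species' net production
  # (or the reaction's flux)
  if (id %in% net$reactions$id) {
    w <- stats::setNames(numeric(nrow(net$reactions)), net$reactions$id)
    w[id] <- 1
    return(w)
  }
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop(sprintf("'%s' is neither a reaction nor a metabolite id", id))
  stats::setNames(net$S[i, ], net$reactions$id)
}

#' Maximum product yield per unit substrate
#'
#' Linear-programming maximum of the product's net production rate with the
#' substrate's net consumption fixed to one unit. Both arguments accept an
#' exchange reaction id or an extracellular metabolite id. The value is
#' scale-invariant in the uptake normalization and, on any network whose
#' elementary flux modes are enumerable, equals the maximum over EFM yields.
#'
#' @param net A `metabolic_network`.
#' @param product_id Product exchange reaction or extracellular metabolite id.
#' @param substrate_id Substrate exchange reaction or extracellular metabolite id.
#' @param unbounded_fluxes When `TRUE` (default) internal flux upper bounds
#'   are released so the yield is a property of the stoichiometric cone.
#' @return Maximum yield (mol product per mol substrate).
#' @export
max_yield <- function(net, product_id, substrate_id, unbounded_fluxes = TRUE) {
  wp <- resolve_exchange(net, product_id)
  ws <- resolve_exchange(net, substrate_id)
  r <- net$reactions
  lb <- r$lb; ub <- r$ub
  # release finite capacity bounds but keep closed reactions (ub == 0) closed
  if (unbounded_fluxes) ub[ub > 0] <- Inf
  # substrate net production = -1 (one unit consumed)
  sgn <- if (substrate_id %in% r$id) 1 else -1
  Si <- stoichiometric_matrix(net, "intracellular")
  sol <- solve_lp(wp, rbind(Si, ws), c(rep(0, nrow(Si)), sgn * 1),
                  lb, ub, maximize = TRUE)
  if (sol$status != "optimal") {
    stop(sprintf("yield LP %s with substrate uptake fixed at 1", sol$status))
  }
  sol$objective
}

#' Yields from a flux vector
#'
#' Divides every flux (and every extracellular net production rate) by the
#' absolute substrate uptake rate.
#'
#' @param v A `flux_vector` (or named numeric vector of fluxes).
#' @param net The network the fluxes belong to.
#' @param substrate_id Exchange reaction or extracellular metabolite id.
#' @return A `yield_vector`: named yields of extracellular species
#'   (mol per mol substrate) with attribute `fluxes` holding flux yields.
#' @export
yields_from_flux <- function(v, net, substrate_id) {
  vals <- if (inherits(v, "flux_vector")) v$values else v
  ws <- resolve_exchange(net, substrate_id)
  uptake <- abs(sum(ws * vals[names(ws)]))
  if (!is.finite(uptake) || uptake < 1e-12) {
    stop("substrate flux is (numerically) zero; yields undefined")
  }
  Se <- stoichiometric_matrix(net, "extracellular")
  ext <- drop(Se %*% vals[colnames(Se)]) / uptake
  structure(ext, fluxes = vals / uptake, substrate_id = substrate_id,
            class = "yield_vector")
}

#' Substrate uptake sweep
#'
#' Replicates the yield-analysis protocol of scanning FBA solutions over a
#' grid of substrate uptake rates (default 0 to 1000 mmol/g_biomass/h in
#' steps of 50; halved/quartered ranges suit disaccharide and tetrameric
#' substrates expressed in hexose equivalents).
#'
#' @param net A `metabolic_network`.
#' @param substrate_id Exchange reaction or extracellular metabolite id.
#' @param objective As in [fba()].
#' @param grid Numeric vector of uptake rates.
#' @return List of `flux_vector`s, one per non-zero grid point.
#' @export
uptake_sweep <- function(net, substrate_id, objective = NULL,
                         grid = seq(0, 1000, by = 50)) {
  ws <- resolve_exchange(net, substrate_id)
  sgn <- if (substrate_id %in% net$reactions$id) 1 else -1
  out <- list()
  for (g in grid[grid > 0]) {
    fv <- fba(net, objective,
              extra_eq = list(A = matrix(ws, 1), b = sgn * g))
    out[[as.character(g)]] <- fv
  }
  out
}
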