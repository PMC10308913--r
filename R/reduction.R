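#' Specification of a flux-consistent network reduction
#'
#' @param protected_metabolites Metabolite ids whose exchange behaviour the
#'   reduction must preserve exactly; must be non-empty and should include
#'   biomass and every measured extracellular species.
#' @param flux_vectors List of `flux_vector`s (or named flux vectors)
#'   computed on the full network; the reduction follows their support.
#' @param blocked_reactions Reaction ids forced out of the reduced network.
#' @param zero_source_cofactors Metabolite ids whose source (uptake)
#'   exchanges are closed before reduction (cofactors not needed as inputs).
#' @return A `reduction_spec`.
#' @export
reduction_spec <- function(protected_metabolites, flux_vectors,
                           blocked_reactions = character(),
                           zero_source_cofactors = character()) {
  if (!length(protected_metabolites)) stop("protected metabolite list is empty")
  if (!length(flux_vectors)) stop("at least one flux vector is required")
  structure(list(protected = protected_metabolites,
                 flux_vectors = flux_vectors,
                 blocked = blocked_reactions,
                 zero_source_cofactors = zero_source_cofactors),
            class = "reduction_spec")
}

#' Append the glucan chain-balance reaction
#'
#' Adds the hypothetical polymerization reaction closing the carbon balance
#' of the glycogen pathway: five glucose-1-phosphate yield five inorganic
#' phosphates plus one (1,4-alpha-D-glucan) chain of five glucose units,
#'
#' \deqn{5\;\mathrm{glc\mbox{-}1\mbox{-}P} \to 5\;\mathrm{P_i} + 1\;\mathrm{glucan}_n}
#'
#' Under the convention that the glucan carries five glucose units (and
#' glycogen six), the reaction is carbon balanced.
#'
#' @param net A `metabolic_network` containing the three species.
#' @param glc1p_id,pi_id,glucan_id Metabolite ids (defaults match the
#'   packaged reduced-network fixture).
#' @param id Reaction id for the new reaction.
#' @return The extended network.
#' @export
add_glucan_balance_reaction <- function(net, glc1p_id = "glc1p[c]",
                                        pi_id = "pi[c]", glucan_id = "glucan[c]",
                                        id = "glucan_balance") {
  needed <- c(glc1p_id, pi_id, glucan_id)
  missing <- setdiff(needed, net$metabolites$id)
  if (length(missing)) {
    stop(sprintf("glucan balance reaction needs missing species: %s",
                 paste(missing, collapse = ", ")))
  }
  stoich <- stats::setNames(c(-5, 5, 1), c(glc1p_id, pi_id, glucan_id))
  add_reaction(net, id, stoich, reversible = FALSE, lb = 0, ub = 1000)
}

#' Build a lumped biomass reaction
#'
#' Collapses the biosynthetic subnetwork behind a biomass reaction into a
#' single reaction over central precursors (e.g. pyruvate, fructose-6P):
#' every consumed intermediate that is not a precursor is substituted by a
#' producing reaction drawn from the essential-reaction list, summing
#' cofactor usage along the way. The biomass product is then assigned the
#' target elemental composition and its coefficient is rescaled so the
#' lumped reaction closes the carbon balance, which fixes the biomass mass
#' per C-mole at the target value (default 26.401 g/mol_C).
#'
#' @param net A `metabolic_network`.
#' @param precursor_ids Metabolite ids accepted as currencies of the lumped
#'   reaction (not substituted further).
#' @param essential_ids Reaction ids that may be used for substitution.
#' @param biomass_rxn_id Biomass reaction to lump (defaults to the network
#'   objective).
#' @param biomass_id Id of the biomass species (default `"biomass[e]"`).
#' @param target_mass_per_c Target biomass mass per C-mole (g/mol_C).
#' @param target_formula Elemental composition assigned to biomass.
#' @param max_steps Substitution step cap (cycle guard).
#' @return A list with `stoich` (named coefficients of the lumped reaction),
#'   `biomass_coef`, `used_reactions`.
#' @export
build_lumped_biomass <- function(net, precursor_ids, essential_ids,
                                 biomass_rxn_id = NULL,
                                 biomass_id = "biomass[e]",
                                 target_mass_per_c = biomass_g_per_mol_c,
                                 target_formula = biomass_formula,
                                 max_steps = 200L) {
  if (is.null(biomass_rxn_id)) biomass_rxn_id <- net$objective
  if (is.null(biomass_rxn_id)) stop("no biomass reaction given")
  j <- match(biomass_rxn_id, net$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction '%s'", biomass_rxn_id))
  stoich <- net$S[, j]
  names(stoich) <- net$metabolites$id
  used <- biomass_rxn_id
  is_internal <- stats::setNames(net$metabolites$compartment == "c",
                                 net$metabolites$id)
  for (step in seq_len(max_steps)) {
    cand <- names(stoich)[stoich < -ZERO_COEF_TOL & is_internal[names(stoich)] &
                          !(names(stoich) %in% precursor_ids)]
    if (!length(cand)) break
    m <- sort(cand)[1]
    producers <- which(net$S[m, ] > ZERO_COEF_TOL &
                       net$reactions$id %in% essential_ids &
                       net$reactions$id != biomass_rxn_id)
    if (!length(producers)) {
      stop(sprintf("biomass component '%s' has no producing reaction among the essential set", m))
    }
    p <- producers[order(net$reactions$id[producers])][1]
    lambda <- -stoich[m] / net$S[m, p]
    stoich <- stoich + lambda * net$S[, p]
    used <- union(used, net$reactions$id[p])
    stoich[abs(stoich) < 1e-12] <- 0
    if (step == max_steps) stop("lumped-biomass substitution did not terminate (cycle?)")
  }
  # carbon closure: rescale the biomass coefficient so that carbon consumed
  # equals carbon in biomass plus carbon in byproducts
  fmap <- stats::setNames(net$metabolites$formula, net$metabolites$id)
  carbon_of <- function(id) {
    if (id == biomass_id) return(0)
    cc <- carbon_count(fmap[[id]])
    if (is.na(cc)) 0 else cc # pseudo-species contribute no carbon
  }
  others <- setdiff(names(stoich)[abs(stoich) > 0], biomass_id)
  net_c <- sum(vapply(others, function(id) stoich[[id]] * carbon_of(id), 0))
  bio_c <- carbon_count(target_formula)
  if (net_c >= 0) stop("lumped reaction consumes no net carbon; cannot scale biomass")
  bcoef <- -net_c / bio_c
  stoich[biomass_id] <- bcoef
  stoich <- stoich[abs(stoich) > ZERO_COEF_TOL]
  list(stoich = stoich, biomass_coef = unname(bcoef), used_reactions = used,
       biomass_formula = target_formula,
       mass_per_c = molar_mass_per_carbon(target_formula))
}

#' Flux-consistent network reduction with protected metabolites
#'
#' Reduces a network by exact matrix algebra along supplied flux vectors:
#' reactions carrying zero flux in every vector (and explicitly blocked
#' ones) are dropped, and every unprotected intracellular metabolite is
#' eliminated by lumping a pivot reaction into the other reactions that use
#' it (a column operation that provably leaves the net production rate of
#' every remaining metabolite unchanged for any steady-state flux vector).
#' Elimination order is deterministic: fewest-connected metabolite first,
#' ties broken by id.
#'
#' @param net A `metabolic_network` (irreversible; split reversibles first).
#' @param spec A [reduction_spec()].
#' @param tol Numeric tolerance for zero flux / zero coefficient.
#' @return A `reduced_network`: list with `network`, `mapping` (reduced
#'   reaction id -> original reaction ids), `reduced_flux` (one named flux
#'   vector per input vector).
#' @export
reduce_network <- function(net, spec, tol = 1e-9) {
  stopifnot(inherits(spec, "reduction_spec"))
  V <- vapply(spec$flux_vectors, function(fv) {
    vals <- if (inherits(fv, "flux_vector")) fv$values else fv
    if (inherits(fv, "flux_vector") && fv$status != "optimal") {
      stop("reduction received a non-optimal flux vector")
    }
    as.numeric(vals[net$reactions$id])
  }, numeric(nrow(net$reactions)))
  V <- matrix(V, nrow = nrow(net$reactions))
  rownames(V) <- net$reactions$id
  Si <- stoichiometric_matrix(net, "intracellular")
  res <- if (nrow(Si)) apply(abs(Si %*% V), 2, max) else numeric(ncol(V))
  if (any(res > 1e-6)) {
    stop(sprintf("flux vector %d is not at intracellular steady state (residual %.3g)",
                 which.max(res), max(res)))
  }
  unreachable <- spec$protected[vapply(spec$protected, function(m) {
    i <- match(m, net$metabolites$id)
    !is.na(i) && all(abs(net$S[i, ] %*% V) < tol)
  }, TRUE)]
  if (length(unreachable)) {
    warning(sprintf("protected metabolite(s) carry no flux in any supplied vector: %s",
                    paste(unreachable, collapse = ", ")))
  }

  active <- apply(abs(V), 1, max) > tol & !(net$reactions$id %in% spec$blocked)
  S <- net$S[, active, drop = FALSE]
  V <- V[active, , drop = FALSE]
  mapping <- stats::setNames(as.list(colnames(S)), colnames(S))

  met_ids <- net$metabolites$id
  internal <- net$metabolites$compartment == "c"
  eliminate <- met_ids[internal & !(met_ids %in% spec$protected)]

  repeat {
    conn <- vapply(eliminate, function(m) sum(abs(S[m, ]) > tol), 0L)
    todo <- eliminate[conn > 0L]
    if (!length(todo)) break
    m <- todo[order(conn[conn > 0L], todo)][1]
    touching <- which(abs(S[m, ]) > tol)
    # pivot: largest coefficient magnitude, ties by reaction id
    piv <- touching[order(-abs(S[m, touching]), colnames(S)[touching])][1]
    if (length(touching) == 1L) {
      if (max(abs(V[piv, ])) > 1e-6) {
        stop(sprintf("metabolite '%s' is produced by a single active reaction; flux vectors are inconsistent", m))
      }
      mapping[[colnames(S)[piv]]] <- NULL
      S <- S[, -piv, drop = FALSE]; V <- V[-piv, , drop = FALSE]
      eliminate <- setdiff(eliminate, m)
      next
    }
    for (r in setdiff(touching, piv)) {
      lam <- S[m, r] / S[m, piv]
      S[, r] <- S[, r] - lam * S[, piv]
      mapping[[colnames(S)[r]]] <- union(mapping[[colnames(S)[r]]],
                                         mapping[[colnames(S)[piv]]])
    }
    S[abs(S) < 1e-12] <- 0
    keep <- setdiff(seq_len(ncol(S)), piv)
    mapping[[colnames(S)[piv]]] <- NULL
    S <- S[, keep, drop = FALSE]
    V <- V[keep, , drop = FALSE]
    eliminate <- setdiff(eliminate, m)
  }

  # drop zero columns (cancelled conversions) and merge proportional columns
  nz <- apply(abs(S), 2, max) > tol
  for (id in colnames(S)[!nz]) mapping[[id]] <- NULL
  S <- S[, nz, drop = FALSE]; V <- V[nz, , drop = FALSE]
  j <- 1L
  while (j < ncol(S)) {
    k <- j + 1L
    while (k <= ncol(S)) {
      a <- S[, j]; b <- S[, k]
      ia <- which.max(abs(a))
      ratio <- b[ia] / a[ia]
      if (ratio > tol && max(abs(b - ratio * a)) < 1e-8 * max(abs(b), 1)) {
        V[j, ] <- V[j, ] + ratio * V[k, ]
        mapping[[colnames(S)[j]]] <- union(mapping[[colnames(S)[j]]],
                                           mapping[[colnames(S)[k]]])
        mapping[[colnames(S)[k]]] <- NULL
        keep <- setdiff(seq_len(ncol(S)), k)
        S <- S[, keep, drop = FALSE]; V <- V[keep, , drop = FALSE]
      } else k <- k + 1L
    }
    j <- j + 1L
  }

  met_keep <- apply(abs(S), 1, max) > tol | met_ids %in% spec$protected
  S2 <- S[met_keep, , drop = FALSE]
  mets <- net$metabolites[met_keep, , drop = FALSE]
  rxns <- data.frame(id = colnames(S2),
                     reversible = FALSE,
                     lb = 0, ub = Inf,
                     stringsAsFactors = FALSE)
  red <- metabolic_network(mets, rxns, S2,
                           objective = if (!is.null(net$objective) &&
                                           net$objective %in% colnames(S2))
                             net$objective else NULL)
  reduced_flux <- lapply(seq_len(ncol(V)), function(k) {
    stats::setNames(V[, k], colnames(S2))
  })
  structure(list(network = red, mapping = mapping,
                 reduced_flux = reduced_flux,
                 protected = spec$protected),
            class = "reduced_network")
}

#' @export
print.reduced_network <- function(x, ...) {
  cat(sprintf("reduced_network: %d reactions (from %d originals), %d metabolites, %d protected\n",
              nrow(x$network$reactions),
              length(unique(unlist(x$mapping))),
              nrow(x$network$metabolites), length(x$protected)))
  invisible(x)
}

#' Net production rates of protected metabolites under a flux vector
#'
#' Used to assert the defining invariant of the reduction: for every input
#' flux vector, the exchange rate of each protected metabolite is the same
#' in the full and in the reduced network.
#'
#' @param net A `metabolic_network`.
#' @param v Named flux vector (or `flux_vector`).
#' @param protected Metabolite ids.
#' @return Named numeric vector of net production rates.
#' @export
protected_exchange_rates <- function(net, v, protected) {
  vals <- if (inherits(v, "flux_vector")) v$values else v
  out <- stats::setNames(numeric(length(protected)), protected)
  for (m in protected) {
    i <- match(m, net$metabolites$id)
    out[m] <- if (is.na(i)) 0 else sum(net$S[i, ] * vals[colnames(net$S)])
  }
  out
}
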