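#' Construct a metabolic network
#'
#' A `metabolic_network` couples a metabolite table, a reaction table and a
#' dense stoichiometric matrix `S` (rows = metabolites, columns = reactions).
#' Metabolites are tagged with a compartment: `"c"` (cytosolic, balanced at
#' steady state) or `"e"` (extracellular / unbalanced). The row blocks of `S`
#' belonging to the two compartments are the matrices `Si` and `Se` of
#' intracellular and extracellular species.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (`"c"` or `"e"`) and optionally `formula` (string; `NA` marks a
#'   pseudo-species without elemental formula, e.g. "salts" or biomass).
#' @param reactions data.frame with columns `id`, `reversible` (logical),
#'   `lb`, `ub` (flux bounds, mmol/g_biomass/h) and optionally `gene_rule`.
#' @param S numeric matrix, one row per metabolite (in `metabolites` order),
#'   one column per reaction; negative coefficients consume.
#' @param objective optional reaction id used as default FBA objective.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, S, objective = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- NA_character_
  S <- as.matrix(S)
  dimnames(S) <- list(metabolites$id, reactions$id)
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        S = S, objective = objective),
                   class = "metabolic_network")
  validate_network(net)
  net
}

ZERO_COEF_TOL <- 1e-12

#' Validate the structural invariants of a network
#'
#' Checks id uniqueness, compartment tags, bound consistency of
#' irreversible reactions, non-empty reaction stoichiometries and the
#' row partition of `S` into `Si` and `Se`.
#'
#' @param net A `metabolic_network`.
#' @return The network, invisibly; errors describe the first violation.
#' @export
validate_network <- function(net) {
  m <- net$metabolites; r <- net$reactions; S <- net$S
  if (anyDuplicated(m$id)) {
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  }
  if (anyDuplicated(r$id)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(r$id[duplicated(r$id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(m$compartment), c("c", "e"))
  if (length(bad)) stop(sprintf("unknown compartment(s): %s",
                                paste(bad, collapse = ", ")))
  if (nrow(S) != nrow(m) || ncol(S) != nrow(r)) {
    stop("S dimensions do not match metabolite/reaction tables")
  }
  if (any(!is.finite(S))) stop("non-finite stoichiometric coefficient")
  empty <- colSums(abs(S) > ZERO_COEF_TOL) == 0
  if (any(empty)) stop(sprintf("reaction(s) with empty stoichiometry: %s",
                               paste(r$id[empty], collapse = ", ")))
  irrev_neg <- !r$reversible & r$lb < 0
  if (any(irrev_neg)) {
    stop(sprintf("irreversible reaction(s) with negative lower bound: %s",
                 paste(r$id[irrev_neg], collapse = ", ")))
  }
  if (any(r$lb > r$ub)) stop("reaction with lb > ub")
  if (!is.null(net$objective) && !net$objective %in% r$id) {
    stop(sprintf("objective reaction '%s' not in network", net$objective))
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d reactions, %d metabolites (%d intracellular, %d extracellular)\n",
              nrow(x$reactions), nrow(x$metabolites),
              sum(x$metabolites$compartment == "c"),
              sum(x$metabolites$compartment == "e")))
  if (!is.null(x$objective)) cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' Returns `S` (all rows), `Si` (intracellular rows, compartment `"c"`) or
#' `Se` (extracellular rows, compartment `"e"`). Row order follows the
#' metabolite table; the intracellular and extracellular row sets are
#' disjoint and together cover all rows.
#'
#' @param net A `metabolic_network`.
#' @param scope `"all"`, `"intracellular"` or `"extracellular"`.
#' @return Numeric matrix with metabolite ids as row names.
#' @export
stoichiometric_matrix <- function(net,
                                  scope = c("all", "intracellular", "extracellular")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
                 all = rep(TRUE, nrow(net$metabolites)),
                 intracellular = net$metabolites$compartment == "c",
                 extracellular = net$metabolites$compartment == "e")
  net$S[keep, , drop = FALSE]
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Every reversible reaction `r` is decoupled into `r_f` (original
#' stoichiometry, bounds `[0, ub]`) and `r_b` (negated stoichiometry, bounds
#' `[0, -lb]`). Irreversible reactions pass through unchanged, so the result
#' has `n_irreversible + 2 * n_reversible` reactions, all with non-negative
#' flux ranges — the form required for elementary-flux-mode enumeration.
#'
#' @param net A `metabolic_network`.
#' @return A `metabolic_network` with only irreversible reactions. The
#'   forward/backward pairing is recorded in attribute `"split_pairs"`.
#' @export
split_reversible <- function(net) {
  r <- net$reactions
  if (!any(r$reversible)) {
    attr(net, "split_pairs") <- data.frame(fwd = character(), bwd = character())
    return(net)
  }
  cols <- list(); ids <- character(); lb <- ub <- numeric()
  rev_flag <- logical(); gene <- character()
  pairs_f <- pairs_b <- character()
  for (i in seq_len(nrow(r))) {
    if (r$reversible[i]) {
      idf <- paste0(r$id[i], "_f"); idb <- paste0(r$id[i], "_b")
      cols[[idf]] <- net$S[, i]
      cols[[idb]] <- -net$S[, i]
      ids <- c(ids, idf, idb)
      lb <- c(lb, 0, 0)
      ub <- c(ub, max(r$ub[i], 0), max(-r$lb[i], 0))
      rev_flag <- c(rev_flag, FALSE, FALSE)
      gene <- c(gene, r$gene_rule[i], r$gene_rule[i])
      pairs_f <- c(pairs_f, idf); pairs_b <- c(pairs_b, idb)
    } else {
      cols[[r$id[i]]] <- net$S[, i]
      ids <- c(ids, r$id[i])
      lb <- c(lb, max(r$lb[i], 0)); ub <- c(ub, r$ub[i])
      rev_flag <- c(rev_flag, FALSE)
      gene <- c(gene, r$gene_rule[i])
    }
  }
  S2 <- do.call(cbind, cols)
  out <- metabolic_network(net$metabolites,
                           data.frame(id = ids, reversible = rev_flag,
                                      lb = lb, ub = ub, gene_rule = gene,
                                      stringsAsFactors = FALSE),
                           S2, objective = if (!is.null(net$objective) &&
                                               net$objective %in% ids)
                             net$objective else NULL)
  attr(out, "split_pairs") <- data.frame(fwd = pairs_f, bwd = pairs_b,
                                         stringsAsFactors = FALSE)
  out
}

#' Merge forward/backward pairs back into reversible reactions
#'
#' Inverse of [split_reversible()] up to net stoichiometry: each `_f`/`_b`
#' pair collapses into one reversible reaction. Used mainly to assert the
#' round-trip property in tests.
#'
#' @param net A split `metabolic_network` carrying the `"split_pairs"` attribute.
#' @return A `metabolic_network`.
#' @export
merge_split_reactions <- function(net) {
  pairs <- attr(net, "split_pairs")
  if (is.null(pairs) || !nrow(pairs)) return(net)
  r <- net$reactions
  drop <- match(pairs$bwd, r$id)
  keep <- setdiff(seq_len(nrow(r)), drop)
  S2 <- net$S[, keep, drop = FALSE]
  r2 <- r[keep, , drop = FALSE]
  fi <- match(pairs$fwd, r2$id)
  bi <- match(pairs$bwd, r$id)
  r2$id[fi] <- sub("_f$", "", r2$id[fi])
  r2$reversible[fi] <- TRUE
  r2$lb[fi] <- -r$ub[bi]
  colnames(S2) <- r2$id
  metabolic_network(net$metabolites, r2, S2, objective = net$objective)
}

#' Elemental imbalance of one reaction
#'
#' Net element production of a reaction: for every element, the sum of
#' `coefficient * element count` over the participating metabolites. An
#' all-zero map means the reaction is balanced. Pseudo-species without a
#' formula must be listed in `ignore` explicitly — they are skipped loudly,
#' never silently.
#'
#' @param net A `metabolic_network`.
#' @param reaction_id Reaction to check.
#' @param ignore Character vector of metabolite ids exempt from balancing
#'   (pseudo-species such as `"salts"` or lumped biomass).
#' @param elements Optional subset of elements to report (e.g. `"C"` for
#'   carbon-only accounting in networks where water and protons are implicit).
#' @return Named numeric vector element -> net coefficient.
#' @export
elemental_imbalance <- function(net, reaction_id, ignore = character(),
                                elements = NULL) {
  j <- match(reaction_id, net$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction '%s'", reaction_id))
  coef <- net$S[, j]
  active <- which(abs(coef) > ZERO_COEF_TOL)
  tot <- numeric(0)
  for (i in active) {
    id <- net$metabolites$id[i]
    if (id %in% ignore) next
    f <- parse_formula(net$metabolites$formula[i])
    if (is.null(f)) {
      stop(sprintf("metabolite '%s' has no formula and is not in the ignore list", id))
    }
    for (el in names(f)) {
      tot[el] <- (if (el %in% names(tot)) tot[el] else 0) + coef[i] * f[[el]]
    }
  }
  if (!is.null(elements)) {
    out <- stats::setNames(numeric(length(elements)), elements)
    common <- intersect(elements, names(tot))
    out[common] <- tot[common]
    return(out)
  }
  if (!length(tot)) tot <- c(C = 0)
  tot
}

#' Net stoichiometry of a reaction as a named vector
#' @param net A `metabolic_network`.
#' @param reaction_id Reaction id.
#' @return Named numeric vector over metabolites with non-zero coefficient.
#' @export
reaction_stoich <- function(net, reaction_id) {
  j <- match(reaction_id, net$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction '%s'", reaction_id))
  v <- net$S[, j]
  v[abs(v) > ZERO_COEF_TOL]
}

#' Append a reaction to a network
#' @param net A `metabolic_network`.
#' @param id New reaction id (must be unique).
#' @param stoich Named numeric vector metabolite-id -> coefficient.
#' @param reversible,lb,ub,gene_rule Reaction attributes.
#' @return The extended `metabolic_network`.
#' @export
add_reaction <- function(net, id, stoich, reversible = FALSE,
                         lb = 0, ub = 1000, gene_rule = NA_character_) {
  if (id %in% net$reactions$id) stop(sprintf("duplicate reaction id '%s'", id))
  missing <- setdiff(names(stoich), net$metabolites$id)
  if (length(missing)) {
    stop(sprintf("unknown metabolite(s) in reaction '%s': %s", id,
                 paste(missing, collapse = ", ")))
  }
  col <- stats::setNames(numeric(nrow(net$metabolites)), net$metabolites$id)
  col[names(stoich)] <- stoich
  S2 <- cbind(net$S, col)
  r2 <- rbind(net$reactions,
              data.frame(id = id, reversible = reversible, lb = lb, ub = ub,
                         gene_rule = gene_rule, stringsAsFactors = FALSE))
  metabolic_network(net$metabolites, r2, S2, objective = net$objective)
}
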