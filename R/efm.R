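#' Enumerate elementary flux modes
#'
#' Computes all extreme rays of the flux cone
#' \deqn{\{v \ge 0 : S_i\,v = 0\}}
#' of an irreversible network by the iterative double-description (tableau)
#' method: rays start as the unit fluxes of the positive orthant and are
#' intersected with one intracellular balance hyperplane at a time; at each
#' step rays on opposite sides are combined pairwise, with a combinatorial
#' adjacency test (no third ray's support inside the union of the pair's
#' supports) guarding minimality. The result is exactly the set of
#' elementary flux modes: minimal-support non-negative steady-state flux
#' vectors.
#'
#' Spurious two-cycles arising from forward/backward pairs of a split
#' reversible reaction (zero net conversion) are removed post hoc.
#' Arithmetic is floating point with a configurable zero tolerance.
#'
#' @param net An irreversible `metabolic_network` (apply [split_reversible()]
#'   first); an error is raised if reversible reactions remain.
#' @param max_efms Abort (with a partial-progress message) when the working
#'   set of rays exceeds this cap. Default 5e6.
#' @param substrate_id Optional exchange/metabolite id used for canonical
#'   normalization: modes using the substrate are scaled to unit substrate
#'   consumption, all others to unit maximum coefficient.
#' @param drop_two_cycles Remove futile forward/backward two-cycles (default TRUE).
#' @param tol Zero tolerance (default 1e-9).
#' @return An `efm_set`: list with `modes` (reactions x EFMs matrix),
#'   `network_id`, `normalization`.
#' @export
enumerate_efms <- function(net, max_efms = 5e6, substrate_id = NULL,
                           drop_two_cycles = TRUE, tol = 1e-9) {
  if (any(net$reactions$reversible)) {
    stop("network has reversible reactions; call split_reversible() first")
  }
  Si <- stoichiometric_matrix(net, "intracellular")
  n <- ncol(Si)
  R <- diag(1, n)
  if (nrow(Si)) {
    # process balance rows fewest-nonzeros first (deterministic, smaller
    # intermediate ray sets)
    ord <- order(rowSums(abs(Si) > tol), rownames(Si))
    for (k in ord) {
      d <- drop(Si[k, ] %*% R)
      scale <- pmax(apply(abs(R), 2, max), 1)
      zer <- abs(d) <= tol * scale
      pos <- which(!zer & d > 0)
      neg <- which(!zer & d < 0)
      keep <- R[, zer, drop = FALSE]
      if (length(pos) && length(neg)) {
        supports <- R > tol * rep(scale, each = n)
        newrays <- vector("list", length(pos) * length(neg))
        cnt <- 0L
        for (p in pos) for (q in neg) {
          u <- supports[, p] | supports[, q]
          others <- supports[, -c(p, q), drop = FALSE]
          if (ncol(others)) {
            inside <- colSums(others & !u) == 0
            if (any(inside)) next # not adjacent
          }
          ray <- d[p] * R[, q] - d[q] * R[, p]
          ray <- ray / max(abs(ray))
          ray[abs(ray) < tol] <- 0
          cnt <- cnt + 1L
          newrays[[cnt]] <- ray
        }
        if (cnt) keep <- cbind(keep, do.call(cbind, newrays[seq_len(cnt)]))
      }
      if (ncol(keep) > max_efms) {
        stop(sprintf(paste0("elementary-mode cap exceeded: %d candidate rays after ",
                            "%d of %d balance constraints (max_efms = %g)"),
                     ncol(keep), match(k, ord), length(ord), max_efms))
      }
      R <- keep
    }
  }
  if (ncol(R)) {
    # drop duplicates (identical support & proportional) defensively
    R <- R / rep(apply(abs(R), 2, max), each = n)
    key <- apply(round(R, 9), 2, paste, collapse = ",")
    R <- R[, !duplicated(key), drop = FALSE]
  }
  if (drop_two_cycles && ncol(R)) {
    futile <- vapply(seq_len(ncol(R)), function(j) {
      supp <- which(R[, j] > tol)
      length(supp) == 2L &&
        max(abs(net$S[, supp[1]] * R[supp[1], j] +
                net$S[, supp[2]] * R[supp[2], j])) < 1e-7
    }, TRUE)
    R <- R[, !futile, drop = FALSE]
  }
  rownames(R) <- net$reactions$id
  R <- normalize_modes(R, net, substrate_id, tol)
  # deterministic ordering: lexicographic by support pattern
  if (ncol(R)) {
    key <- apply(R > tol, 2, function(s) paste(as.integer(s), collapse = ""))
    R <- R[, order(key, apply(R, 2, paste, collapse = ",")), drop = FALSE]
    colnames(R) <- paste0("efm", seq_len(ncol(R)))
  }
  structure(list(modes = R, network_id = network_identity(net),
                 normalization = if (is.null(substrate_id)) "unit_max" else "unit_substrate",
                 substrate_id = substrate_id),
            class = "efm_set")
}

normalize_modes <- function(R, net, substrate_id, tol = 1e-9) {
  if (!ncol(R)) return(R)
  if (is.null(substrate_id)) {
    return(R / rep(apply(abs(R), 2, max), each = nrow(R)))
  }
  ws <- resolve_exchange(net, substrate_id)
  upt <- abs(drop(ws %*% R))
  for (j in seq_len(ncol(R))) {
    R[, j] <- if (upt[j] > tol) R[, j] / upt[j] else R[, j] / max(abs(R[, j]))
  }
  R
}

network_identity <- function(net) {
  paste0(nrow(net$metabolites), "m:", nrow(net$reactions), "r:",
         substr(paste(net$reactions$id, collapse = "|"), 1, 2000))
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("efm_set: %d elementary flux modes over %d reactions (%s normalization)\n",
              ncol(x$modes), nrow(x$modes), x$normalization))
  invisible(x)
}

#' Number of modes in an efm_set
#' @param x An `efm_set`.
#' @return Integer count.
#' @export
n_efms <- function(x) ncol(x$modes)

#' Filter elementary flux modes by biological criteria
#'
#' Keeps the modes that consume the carbon source, produce biomass, and do
#' not consume glycogen (net glycogen production may be positive or zero).
#' Ids resolve to extracellular metabolite rows of `Se` or to exchange
#' reactions.
#'
#' @param efms An `efm_set`.
#' @param net The network the modes were computed on.
#' @param substrate_id,biomass_id,glycogen_id Species/reactions to test;
#'   `glycogen_id = NULL` skips the glycogen criterion.
#' @param tol Numeric tolerance.
#' @return The filtered `efm_set`.
#' @export
filter_efms <- function(efms, net, substrate_id, biomass_id,
                        glycogen_id = NULL, tol = 1e-9) {
  R <- efms$modes
  if (!ncol(R)) return(efms)
  rate <- function(id) drop(resolve_exchange(net, id) %*% R)
  consumption_sign <- function(id) if (id %in% net$reactions$id) 1 else -1
  subs <- rate(substrate_id) * consumption_sign(substrate_id)
  bio <- rate(biomass_id) * (if (biomass_id %in% net$reactions$id) 1 else 1)
  gly_ok <- if (is.null(glycogen_id)) rep(TRUE, ncol(R)) else rate(glycogen_id) >= -tol
  keep <- subs > tol & bio > tol & gly_ok
  efms$modes <- R[, keep, drop = FALSE]
  if (ncol(efms$modes)) colnames(efms$modes) <- paste0("efm", seq_len(ncol(efms$modes)))
  efms
}

#' Steady-state residual of each mode
#' @param efms An `efm_set`.
#' @param net The network.
#' @return Max-norm residual `Si v` per mode.
#' @export
efm_residuals <- function(efms, net) {
  Si <- stoichiometric_matrix(net, "intracellular")
  if (!ncol(efms$modes)) return(numeric(0))
  apply(abs(Si %*% efms$modes), 2, max)
}
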