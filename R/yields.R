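#' Yield table of an EFM set
#'
#' Projects every elementary flux mode into yield space: the extracellular
#' net conversion `Se e` divided by the mode's substrate uptake. Product
#' yields are mol per mol substrate; the biomass column is converted to
#' grams per mmol substrate using the biomass mass per C-mole (the species'
#' own formula when it has one, otherwise the package biomass constant).
#'
#' @param efms An `efm_set`.
#' @param net The network the modes belong to.
#' @param substrate_id Extracellular substrate (metabolite or exchange id).
#' @param biomass_id Extracellular biomass species id (optional; enables the
#'   gram conversion for that column).
#' @param products Optional subset of extracellular species to report.
#' @return A `yield_table`: data.frame (rows = EFMs, columns = products)
#'   with attributes `substrate_id` and `biomass_id`.
#' @export
efm_yields <- function(efms, net, substrate_id, biomass_id = NULL,
                       products = NULL) {
  R <- efms$modes
  if (!ncol(R)) stop("empty EFM set")
  ws <- resolve_exchange(net, substrate_id)
  upt <- abs(drop(ws %*% R))
  if (any(upt < 1e-12)) {
    stop("EFM with zero substrate flux; filter the set before computing yields")
  }
  Se <- stoichiometric_matrix(net, "extracellular")
  Y <- sweep(Se %*% R, 2, upt, "/")
  if (!is.null(biomass_id) && biomass_id %in% rownames(Y)) {
    i <- match(biomass_id, net$metabolites$id)
    f <- net$metabolites$formula[i]
    # grams per mmol substrate = (mol species / mol substrate) * g/mol / 1000;
    # a formula-less biomass species is C-mol bookkeeping (26.401 g/C-mol)
    gpm <- if (!is.na(f) && nzchar(f)) molar_mass(f) else biomass_g_per_mol_c
    Y[biomass_id, ] <- Y[biomass_id, ] * gpm / 1000
  }
  if (!is.null(products)) {
    missing <- setdiff(products, rownames(Y))
    if (length(missing)) stop(sprintf("unknown product(s): %s",
                                      paste(missing, collapse = ", ")))
    Y <- Y[products, , drop = FALSE]
  }
  yt <- as.data.frame(t(Y))
  attr(yt, "substrate_id") <- substrate_id
  attr(yt, "biomass_id") <- biomass_id
  class(yt) <- c("yield_table", class(yt))
  yt
}

#' Two-dimensional convex hull
#'
#' Counter-clockwise convex hull of a 2-D point set. Duplicate points are
#' collapsed and collinear interior points excluded. Degenerate inputs
#' (single point, all identical, collinear) return the degenerate hull.
#'
#' @param points Two-column matrix/data.frame of points.
#' @return Integer indices (into the input rows) of the hull vertices in
#'   counter-clockwise order.
#' @export
convex_hull_2d <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("convex_hull_2d expects 2-D points")
  if (nrow(pts) < 1L) stop("at least one point required")
  key <- paste(signif(pts[, 1], 12), signif(pts[, 2], 12))
  first <- !duplicated(key)
  idx <- which(first)
  upts <- pts[first, , drop = FALSE]
  if (nrow(upts) == 1L) return(idx[1])
  if (nrow(upts) == 2L) return(idx)
  h <- grDevices::chull(upts[, 1], upts[, 2])
  # ensure counter-clockwise orientation via the signed area
  hx <- upts[h, 1]; hy <- upts[h, 2]
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 < 0) h <- rev(h)
  idx[h]
}

point_in_polygon <- function(p, poly, tol = 1e-9) {
  # ray casting with an edge tolerance: boundary points count as inside
  n <- nrow(poly)
  if (n == 1L) return(max(abs(p - poly[1, ])) <= tol)
  if (n == 2L) {
    d <- poly[2, ] - poly[1, ]
    t <- sum((p - poly[1, ]) * d) / max(sum(d * d), tol)
    proj <- poly[1, ] + pmin(pmax(t, 0), 1) * d
    return(sqrt(sum((p - proj)^2)) <= tol)
  }
  scale <- max(abs(poly), 1)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    cross <- (xj - xi) * (p[2] - yi) - (yj - yi) * (p[1] - xi)
    if (abs(cross) <= tol * scale &&
        p[1] >= min(xi, xj) - tol && p[1] <= max(xi, xj) + tol &&
        p[2] >= min(yi, yj) - tol && p[2] <= max(yi, yj) + tol) return(TRUE)
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- xi + (p[2] - yi) / (yj - yi) * (xj - xi)
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

triangle_area <- function(a, b, cc) {
  abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
}

#' Select vertex EFMs by polygon reduction of yield-space hulls
#'
#' For each 2-D product pair the convex hull of the EFM yield cloud is
#' computed and then reduced to a minimal polygon — hull-vertex triangles
#' are enumerated in increasing area and the first one that still encloses
#' the reference points is taken (the observed yield data when given,
#' otherwise the hull centroid). Ties prefer triangles whose vertices carry
#' higher biomass yield (growth-capable modes). The per-pair selections are
#' unioned and de-duplicated as flux vectors.
#'
#' @param yt A `yield_table` from [efm_yields()].
#' @param product_pairs List of 2-element character vectors naming yield
#'   columns; default: all pairs of available columns.
#' @param data_points Optional matrix/data.frame of observed yield points,
#'   with columns named like the yield table.
#' @param efms Optional `efm_set` used to de-duplicate selected modes as
#'   vectors (recommended).
#' @param biomass_col Column used for the tie-break (default the yield
#'   table's biomass id, if any).
#' @return A `selection_result`: list with `selected_indices`,
#'   `hull_indices` (per pair), `polygon_vertices` (per pair).
#' @export
select_vertex_efms <- function(yt, product_pairs = NULL, data_points = NULL,
                               efms = NULL, biomass_col = attr(yt, "biomass_id")) {
  cols <- colnames(yt)
  if (is.null(product_pairs)) {
    product_pairs <- utils::combn(cols, 2, simplify = FALSE)
  }
  if (nrow(yt) < 3L) {
    return(structure(list(selected_indices = seq_len(nrow(yt)),
                          hull_indices = list(), polygon_vertices = list()),
                     class = "selection_result"))
  }
  hulls <- list(); polys <- list(); selected <- integer()
  for (pair in product_pairs) {
    if (!all(pair %in% cols)) stop(sprintf("unknown yield column(s): %s",
                                           paste(setdiff(pair, cols), collapse = ", ")))
    P <- as.matrix(yt[, pair])
    h <- convex_hull_2d(P)
    key <- paste(pair, collapse = "~")
    hulls[[key]] <- h
    refs <- if (!is.null(data_points) && all(pair %in% colnames(data_points))) {
      as.matrix(data_points[, pair, drop = FALSE])
    } else {
      matrix(colMeans(P[h, , drop = FALSE]), 1)
    }
    tolP <- 1e-9 * max(abs(P), 1)
    if (length(h) <= 3L) {
      polys[[key]] <- h
      selected <- union(selected, h)
      next
    }
    tri <- utils::combn(h, 3, simplify = FALSE)
    areas <- vapply(tri, function(t3) triangle_area(P[t3[1], ], P[t3[2], ], P[t3[3], ]), 0)
    bioscore <- if (!is.null(biomass_col) && biomass_col %in% cols) {
      vapply(tri, function(t3) sum(yt[t3, biomass_col]), 0)
    } else rep(0, length(tri))
    ord <- order(areas, -bioscore)
    chosen <- NULL
    for (k in ord) {
      t3 <- tri[[k]]
      poly <- P[t3, , drop = FALSE]
      if (all(apply(refs, 1, point_in_polygon, poly = poly, tol = tolP))) {
        chosen <- t3
        break
      }
    }
    if (is.null(chosen)) {
      warning(sprintf("no hull-vertex triangle encloses the reference points for pair %s; keeping the full hull", key))
      chosen <- h
    }
    polys[[key]] <- chosen
    selected <- union(selected, chosen)
  }
  selected <- sort(selected)
  if (!is.null(efms)) {
    R <- efms$modes[, selected, drop = FALSE]
    R <- R / rep(apply(abs(R), 2, max), each = nrow(R))
    dup <- duplicated(apply(round(R, 9), 2, paste, collapse = ","))
    selected <- selected[!dup]
  }
  structure(list(selected_indices = selected, hull_indices = hulls,
                 polygon_vertices = polys),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d EFMs selected from %d inspected pairs\n",
              length(x$selected_indices), length(x$hull_indices)))
  invisible(x)
}

#' De-duplicate elementary flux modes across sets
#'
#' Concatenates EFM sets computed on the same network and collapses modes
#' that are equal as flux vectors after unit-maximum normalization
#' (entrywise tolerance 1e-9) — including modes differing only by scale.
#'
#' @param sets List of `efm_set`s sharing one network identity.
#' @param tol Entrywise comparison tolerance.
#' @return A single `efm_set`.
#' @export
deduplicate_efms <- function(sets, tol = 1e-9) {
  if (inherits(sets, "efm_set")) sets <- list(sets)
  ids <- unique(vapply(sets, function(s) s$network_id, ""))
  if (length(ids) != 1L) stop("EFM sets come from different networks")
  R <- do.call(cbind, lapply(sets, function(s) s$modes))
  if (is.null(R) || !ncol(R)) {
    return(structure(list(modes = R, network_id = ids, normalization = "unit_max"),
                     class = "efm_set"))
  }
  R <- R / rep(apply(abs(R), 2, max), each = nrow(R))
  keep <- !logical(ncol(R))
  for (j in seq_len(ncol(R))) {
    if (!keep[j]) next
    if (j < ncol(R)) {
      for (k in seq(j + 1L, ncol(R))) {
        if (keep[k] && max(abs(R[, k] - R[, j])) <= tol) keep[k] <- FALSE
      }
    }
  }
  R <- R[, keep, drop = FALSE]
  colnames(R) <- paste0("efm", seq_len(ncol(R)))
  structure(list(modes = R, network_id = ids, normalization = "unit_max"),
            class = "efm_set")
}
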