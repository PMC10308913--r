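# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: brute-force support enumeration for elementary
# modes, an all-pairs half-plane test for convex hulls, and a fixed-step
# RK4 integrator for ODE cross-checks.

nullspace_basis <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(1, ncol(A)))
  s <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(s$d > tol * max(s$d, 1))
  if (rank == ncol(A)) return(matrix(0, ncol(A), 0))
  s$v[, seq(rank + 1, ncol(A)), drop = FALSE]
}

# all elementary flux modes of an irreversible network by exhaustive
# support enumeration (feasible for <= ~14 reactions)
brute_force_efms <- function(net, tol = 1e-8) {
  Si <- stoichiometric_matrix(net, "intracellular")
  n <- ncol(Si)
  stopifnot(n <= 16)
  cand <- list()
  for (mask in seq_len(2^n - 1)) {
    T <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    N <- nullspace_basis(Si[, T, drop = FALSE])
    if (ncol(N) != 1L) next
    v <- N[, 1]
    if (any(abs(v) < tol)) next # support would be smaller than T
    if (all(v > 0) || all(v < 0)) {
      full <- numeric(n)
      full[T] <- abs(v)
      cand[[length(cand) + 1L]] <- full / max(full)
    }
  }
  if (!length(cand)) return(matrix(0, n, 0, dimnames = list(net$reactions$id, NULL)))
  M <- do.call(cbind, cand)
  supports <- M > tol
  minimal <- vapply(seq_len(ncol(M)), function(j) {
    !any(vapply(seq_len(ncol(M)), function(k) {
      k != j && all(supports[, k] <= supports[, j]) && any(supports[, k] < supports[, j])
    }, TRUE))
  }, TRUE)
  M <- M[, minimal, drop = FALSE]
  M <- M[, !duplicated(apply(supports[, minimal, drop = FALSE], 2, paste, collapse = "")),
         drop = FALSE]
  rownames(M) <- net$reactions$id
  M
}

support_set <- function(M, tol = 1e-8) {
  if (!ncol(M)) return(character())
  M <- M[sort(rownames(M)), , drop = FALSE]
  sort(unname(apply(M > tol, 2, function(s) paste(rownames(M)[s], collapse = ","))))
}

# O(n^3) convex hull: a point is a hull vertex iff some directed line
# through it and another point keeps all remaining points on one side
hull_oracle_vertices <- function(pts, tol = 1e-12) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      if (max(abs(d)) < tol) next
      cr <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
      if (all(cr <= tol * max(1, max(abs(pts))))) { on_hull[i] <- TRUE; break }
    }
  }
  which(on_hull)
}

# strict ray-casting point-in-polygon (no shared code with the package)
ray_cast_inside <- function(p, poly, eps = 1e-12) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- poly[i, 1] + (p[2] - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
      if (p[1] < xint - eps) inside <- !inside
    }
    j <- i
  }
  inside
}

# fixed-step classical Runge-Kutta integrator for cross-checking deSolve
rk4_integrate <- function(rhs, y0, times, n_sub = 200L) {
  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, names(y0)))
  y <- y0
  out[1, ] <- y
  for (k in seq_len(length(times) - 1L)) {
    h <- (times[k + 1] - times[k]) / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[k + 1, ] <- y
  }
  out
}

# shared fixture loaders
fixture_network <- function() example_reduced_network()

glucose_only <- function(net) {
  net$reactions$ub[net$reactions$id %in% c("cellb_upt", "cellu_upt")] <- 0
  net
}

tsv_net <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  on.exit(unlink(tf), add = TRUE)
  load_network(tf, format = "tsv")
}
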