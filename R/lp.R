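#' Solve a bounded linear program
#'
#' Dense two-phase primal simplex with Bland's anti-cycling rule, written
#' for the moderate problem sizes of reduced metabolic networks (tens to a
#' few hundred reactions). Solves
#'
#' \deqn{\max / \min\; c^\top v \quad \mathrm{s.t.}\; A_{eq} v = b_{eq},\;
#'   lb \le v \le ub}
#'
#' Upper bounds may be `Inf`; lower bounds must be finite. Status is
#' reported honestly: `"optimal"`, `"infeasible"` or `"unbounded"` — an
#' infeasible or unbounded problem never returns a silent zero vector.
#'
#' @param obj Objective coefficient vector (length n).
#' @param Aeq Equality constraint matrix (m x n); may have zero rows.
#' @param beq Equality right-hand side (length m).
#' @param lb,ub Variable bounds (finite lb; ub may be `Inf`).
#' @param maximize Maximize (default) or minimize.
#' @param tol Feasibility/pivot tolerance.
#' @return List with `status`, `x` (solution or NA), `objective`.
#' @export
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), ncol = n)
  m <- nrow(Aeq)
  stopifnot(length(beq) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # shift to x = v - lb >= 0
  b0 <- beq - drop(Aeq %*% lb)
  d <- ub - lb
  fin <- which(is.finite(d))
  nf <- length(fin)

  # standard form: [Aeq 0; E_fin I] [x; s] = [b0; d_fin]
  A <- rbind(cbind(Aeq, matrix(0, m, nf)),
             cbind(diag(n)[fin, , drop = FALSE], diag(1, nf)))
  b <- c(b0, d[fin])
  nv <- n + nf
  costs <- c(cc, rep(0, nf))

  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  nrow_tot <- m + nf
  # phase-1 basis: slack variables for bound rows, artificials for eq rows
  art_rows <- seq_len(m)
  n_art <- length(art_rows)
  Aa <- cbind(A, matrix(0, nrow_tot, n_art))
  for (k in seq_along(art_rows)) Aa[art_rows[k], nv + k] <- 1
  basis <- integer(nrow_tot)
  basis[art_rows] <- nv + seq_len(n_art)
  if (nf) {
    for (k in seq_len(nf)) {
      row <- m + k
      scol <- n + k
      if (Aa[row, scol] < 0) { # row was sign-flipped; slack coef -1, needs artificial
        Aa <- cbind(Aa, 0); Aa[row, ncol(Aa)] <- 1
        basis[row] <- ncol(Aa)
      } else basis[row] <- scol
    }
  }
  n_all <- ncol(Aa)
  phase1_cost <- c(rep(0, nv), rep(1, n_all - nv))

  res1 <- simplex_iterate(Aa, b, phase1_cost, basis, tol)
  if (res1$status != "optimal") {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  if (res1$value > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  Tab <- res1$Tab; basis <- res1$basis; rhs <- res1$rhs
  # drive remaining artificials out of the basis (degenerate rows)
  art <- basis > nv
  for (row in which(art)) {
    piv <- which(abs(Tab[row, seq_len(nv)]) > tol)
    if (length(piv)) {
      j <- piv[1]
      pr <- Tab[row, j]
      Tab[row, ] <- Tab[row, ] / pr; rhs[row] <- rhs[row] / pr
      for (i in seq_len(nrow(Tab))) if (i != row && abs(Tab[i, j]) > 0) {
        rhs[i] <- rhs[i] - Tab[i, j] * rhs[row]
        Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[row, ]
      }
      basis[row] <- j
    }
  }
  drop_rows <- which(basis > nv)
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(nrow(Tab)), drop_rows)
    Tab <- Tab[keep, , drop = FALSE]; rhs <- rhs[keep]; basis <- basis[keep]
  }
  Tab <- Tab[, seq_len(nv), drop = FALSE]

  res2 <- simplex_iterate(Tab, rhs, costs, basis, tol, already_reduced = TRUE)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- numeric(nv)
  x[res2$basis] <- res2$rhs
  v <- x[seq_len(n)] + lb
  objective <- sum(obj * v)
  list(status = "optimal", x = v, objective = objective)
}

# tableau simplex minimizing cost' z over {A z = b (rows already reduced to
# basis form when already_reduced), z >= 0}; Bland's rule
simplex_iterate <- function(A, b, cost, basis, tol, already_reduced = FALSE) {
  m <- nrow(A)
  Tab <- A; rhs <- b
  if (!already_reduced) {
    # reduce to canonical form for the given basis (identity on basic columns)
    for (row in seq_len(m)) {
      j <- basis[row]
      pr <- Tab[row, j]
      if (abs(pr) < tol) stop("degenerate starting basis")
      Tab[row, ] <- Tab[row, ] / pr; rhs[row] <- rhs[row] / pr
      for (i in seq_len(m)) if (i != row && abs(Tab[i, j]) > 0) {
        rhs[i] <- rhs[i] - Tab[i, j] * rhs[row]
        Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[row, ]
      }
    }
  }
  maxiter <- 200L * (m + ncol(A))
  for (it in seq_len(maxiter)) {
    red <- cost - drop(cost[basis] %*% Tab)
    red[basis] <- 0
    enter <- which(red < -1e-9)
    if (!length(enter)) {
      return(list(status = "optimal", Tab = Tab, rhs = rhs, basis = basis,
                  value = sum(cost[basis] * rhs)))
    }
    j <- enter[1] # Bland
    col <- Tab[, j]
    cand <- which(col > tol)
    if (!length(cand)) {
      return(list(status = "unbounded", Tab = Tab, rhs = rhs, basis = basis,
                  value = -Inf))
    }
    ratios <- rhs[cand] / col[cand]
    rmin <- min(ratios)
    ties <- cand[ratios <= rmin + tol]
    row <- ties[which.min(basis[ties])] # Bland on leaving variable
    pr <- Tab[row, j]
    Tab[row, ] <- Tab[row, ] / pr; rhs[row] <- rhs[row] / pr
    for (i in seq_len(m)) if (i != row && abs(Tab[i, j]) > 0) {
      rhs[i] <- rhs[i] - Tab[i, j] * rhs[row]
      Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[row, ]
    }
    rhs[abs(rhs) < 1e-12] <- 0
    basis[row] <- j
  }
  stop("simplex iteration limit reached")
}
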