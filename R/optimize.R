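# Generic linear-programming front end.
# Constraints: Aeq x = beq, G x >= h, x free. Returns list(x, value, status),
# status in "optimal", "infeasible", "unbounded".
#
# Solved by an exact two-phase revised simplex with Bland's anticycling rule
# (problems in this package are tiny: tens of variables and rows, so dense
# refactorization each iteration is cheap and numerically clean).
solve_lp <- function(cvec, Aeq = NULL, beq = NULL, G = NULL, h = NULL,
                     maximize = FALSE) {
  n <- length(cvec)
  obj <- if (maximize) -cvec else cvec
  # standard form: variables [x+, x-, s] >= 0; rows [Aeq; G] with slacks -s
  # on the G rows (G x - s = h).
  m_eq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  m_in <- if (is.null(G)) 0L else nrow(G)
  A <- matrix(0, m_eq + m_in, 2L * n + m_in)
  b <- numeric(m_eq + m_in)
  if (m_eq) {
    A[seq_len(m_eq), seq_len(n)] <- unname(Aeq)
    A[seq_len(m_eq), n + seq_len(n)] <- -unname(Aeq)
    b[seq_len(m_eq)] <- unname(beq)
  }
  if (m_in) {
    r <- m_eq + seq_len(m_in)
    A[r, seq_len(n)] <- unname(G)
    A[r, n + seq_len(n)] <- -unname(G)
    A[cbind(r, 2L * n + seq_len(m_in))] <- -1
    b[r] <- unname(h)
  }
  cc <- c(obj, -obj, numeric(m_in))
  res <- simplex_two_phase(cc, A, b)
  if (res$status != "optimal")
    return(list(x = NULL, value = NA_real_, status = res$status))
  x <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(x) <- names(cvec)
  list(x = x, value = sum(cvec * x), status = "optimal")
}

# min c'x s.t. Ax = b, x >= 0 (b any sign; rows are flipped internally).
simplex_two_phase <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); nv <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  scale_ <- max(1, max(abs(b)))
  # phase 1: artificial basis
  A1 <- cbind(A, diag(m))
  c1 <- c(numeric(nv), rep(1, m))
  basis <- nv + seq_len(m)
  p1 <- simplex_core(c1, A1, b, basis, allowed = seq_len(nv + m), tol = tol)
  if (p1$status == "unbounded")
    stop("internal error: phase-1 LP cannot be unbounded")
  if (p1$value > 1e-7 * scale_)
    return(list(status = "infeasible"))
  basis <- p1$basis
  # Drive leftover artificials (basic at zero) out of the basis: pivot in a
  # structural column with a nonzero entry in the artificial's tableau row;
  # if none exists the corresponding constraint row is redundant and is
  # dropped together with its artificial. Without this step a zero-valued
  # basic artificial could regrow during phase 2.
  repeat {
    art_pos <- which(basis > nv)
    if (!length(art_pos)) break
    i <- art_pos[1L]
    B <- A1[, basis, drop = FALSE]
    tab_row <- solve(B, A1[, seq_len(nv), drop = FALSE])[i, ]
    j <- which(abs(tab_row) > 1e-7 & !(seq_len(nv) %in% basis))
    if (length(j)) {
      basis[i] <- j[1L]
    } else {
      row_drop <- basis[i] - nv         # artificial k sits in row k
      keep <- setdiff(seq_len(nrow(A1)), row_drop)
      # renumber artificial columns consistently by rebuilding them
      A1 <- cbind(A1[keep, seq_len(nv), drop = FALSE],
                  diag(length(keep)))
      old_art <- setdiff(seq_len(m), row_drop)
      b <- b[keep]
      basis <- basis[-i]
      is_art <- basis > nv
      basis[is_art] <- nv + match(basis[is_art] - nv, old_art)
      m <- length(keep)
    }
  }
  p2 <- simplex_core(c(cc, numeric(m)), A1, b, basis,
                     allowed = seq_len(nv), tol = tol)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(nv + m)
  x[p2$basis] <- p2$xB
  list(status = "optimal", x = x[seq_len(nv)],
       value = sum(cc * x[seq_len(nv)]))
}

# Revised simplex with Bland's rule; fresh dense solves per iteration.
simplex_core <- function(cc, A, b, basis, allowed, tol = 1e-9,
                         max_iter = 20000L) {
  allow <- logical(ncol(A)); allow[allowed] <- TRUE
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    xB <- solve(B, b)
    y <- solve(t(B), cc[basis])
    red <- cc - drop(crossprod(A, y))
    red[basis] <- 0
    cand <- which(allow & red < -tol * max(1, max(abs(cc))))
    if (!length(cand))
      return(list(status = "optimal", basis = basis, xB = xB,
                  value = sum(cc[basis] * xB)))
    j <- min(cand)                          # Bland: smallest index enters
    d <- solve(B, A[, j])
    pos <- which(d > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- xB[pos] / d[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol * max(1, rmin)]
    leave <- ties[which.min(basis[ties])]   # Bland: smallest basic leaves
    basis[leave] <- j
  }
  stop("simplex iteration limit exceeded")
}

#' Flux balance analysis: maximize a linear flux objective
#'
#' Solves the linear program `max c' Phi` subject to the steady-state
#' equalities `E Phi = f` and inequalities `G Phi >= h` of a flux problem.
#' When the optimal face is degenerate (multiple optimal vertices) any one
#' vertex is returned and a warning is raised; use the sampling module for
#' the geometry of the optimal/feasible set.
#'
#' @param problem a `flux_problem`
#' @param check_degenerate if TRUE (default), probe for alternate optima by
#'   re-optimizing a perturbed objective on the optimal face
#' @return list with `flux` (named optimal flux vector) and `objective`
#'   (optimal value)
#' @export
fba_optimize <- function(problem, check_degenerate = TRUE) {
  stopifnot(inherits(problem, "flux_problem"))
  cvec <- problem$objective
  res <- solve_lp(cvec, Aeq = problem$E, beq = problem$f,
                  G = problem$G, h = problem$h, maximize = TRUE)
  if (res$status == "infeasible")
    stop("flux problem is infeasible: no flux vector satisfies the ",
         "steady-state and bound constraints")
  if (res$status == "unbounded")
    stop("objective is unbounded over the feasible flux set")
  flux <- res$x
  names(flux) <- problem$reactions
  if (check_degenerate && any(cvec != 0)) {
    # optimize a generic secondary direction on the optimal face
    Aeq2 <- rbind(problem$E, matrix(cvec, 1))
    beq2 <- c(problem$f, res$value)
    probe <- stats::setNames(sin(seq_along(cvec)), names(cvec)) # fixed generic
    alt <- solve_lp(probe, Aeq = Aeq2, beq = beq2,
                    G = problem$G, h = problem$h, maximize = TRUE)
    if (alt$status == "optimal" &&
        max(abs(alt$x - flux)) > 1e-6 * max(1, max(abs(flux))))
      warning("degenerate LP optimum: alternate optimal vertices exist")
  }
  list(flux = flux, objective = res$value)
}

#' Least squares under equality and inequality constraints
#'
#' Minimizes the inverse-variance weighted residual
#' `sum_r (A_r Phi - b_r)^2 / var_r` over flux vectors satisfying
#' `E Phi = f` and `G Phi >= h`. The equalities are eliminated by a
#' null-space (orthonormal basis) change of variables; the reduced problem
#' is an inequality-constrained quadratic program. When the reduced Hessian
#' is singular (targets do not determine all free directions) the
#' minimum-norm minimizer of the reduced variable is returned in the
#' unconstrained case, and a small ridge regularizer selects among
#' minimizers in the inequality-constrained case.
#'
#' @param problem a `flux_problem` with at least one soft target row
#'   (`A`, `b`, `var`)
#' @return named flux vector
#' @export
lsei_solve <- function(problem) {
  stopifnot(inherits(problem, "flux_problem"))
  if (nrow(problem$A) == 0L)
    stop("flux problem has no soft target rows (A, b); nothing to fit")
  n <- length(problem$reactions)
  W <- 1 / problem$var
  Aw <- problem$A * sqrt(W)          # row-scaled
  bw <- problem$b * sqrt(W)

  # particular solution + null space of equalities
  if (nrow(problem$E) > 0L) {
    phi0 <- drop(MASS::ginv(problem$E) %*% problem$f)  # min-norm particular solution
    if (max(abs(problem$E %*% phi0 - problem$f)) > 1e-8 * max(1, max(abs(problem$f))))
      stop("equality constraints are inconsistent")
    N <- MASS::Null(t(problem$E))
    if (length(N) == 0L) N <- matrix(0, n, 0)
  } else {
    phi0 <- numeric(n)
    N <- diag(n)
  }
  if (ncol(N) == 0L) {
    # fully determined by equalities; just check inequalities
    if (nrow(problem$G) && any(problem$G %*% phi0 - problem$h < -1e-8))
      stop("constraint set infeasible: equalities pin a point violating inequalities")
    return(stats::setNames(drop(phi0), problem$reactions))
  }

  H <- crossprod(Aw %*% N)
  g <- crossprod(Aw %*% N, bw - Aw %*% phi0)
  scale_ <- max(diag(H), 1)

  unconstrained_z <- function() {
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > 1e-12 * scale_
    # minimum-norm least-squares solution in z
    drop(ev$vectors[, pos, drop = FALSE] %*%
           ((t(ev$vectors[, pos, drop = FALSE]) %*% g) / ev$values[pos]))
  }

  z <- unconstrained_z()
  feasible <- function(zz) {
    if (nrow(problem$G) == 0L) return(TRUE)
    all(problem$G %*% (phi0 + N %*% zz) - problem$h >= -1e-9)
  }
  if (!feasible(z)) {
    Gz <- problem$G %*% N
    hz <- problem$h - problem$G %*% phi0
    Hq <- H
    if (min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) <
        1e-10 * scale_)
      Hq <- H + (1e-9 * scale_) * diag(ncol(N))
    qp <- tryCatch(
      pracma::quadprog(C = Hq, d = -drop(g), A = -Gz, b = -drop(hz)),
      error = function(e) stop("constrained least-squares failed: ",
                               conditionMessage(e)))
    z <- qp$xmin
    if (!feasible(z) &&
        any(problem$G %*% (phi0 + N %*% z) - problem$h < -1e-6))
      stop("constraint set appears infeasible for the least-squares fit")
  }
  phi <- drop(phi0 + N %*% z)
  stats::setNames(phi, problem$reactions)
}
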