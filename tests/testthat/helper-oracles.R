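# Independent oracles used across the suite. These deliberately share no
# code with the package's production paths: conditioning is done by the
# block-partitioned multivariate-normal formula (the package absorbs
# evidence sequentially by rank-one updates), and the QP oracle enumerates
# active sets and solves KKT systems directly (the package reduces by a
# null-space basis and calls an inequality-QP routine).

# Condition N(mu, Sigma) on x[ev_idx] = ev_val; returns means/vars of all
# coordinates (evidence coordinates pinned at their values, variance 0).
condition_mvn_oracle <- function(mu, Sigma, ev_idx, ev_val) {
  keep <- setdiff(seq_along(mu), ev_idx)
  S22 <- Sigma[ev_idx, ev_idx, drop = FALSE]
  S12 <- Sigma[keep, ev_idx, drop = FALSE]
  delta <- solve(S22, ev_val - mu[ev_idx])
  mu_c <- mu
  mu_c[keep] <- mu[keep] + drop(S12 %*% delta)
  mu_c[ev_idx] <- ev_val
  var_c <- numeric(length(mu))
  Scond <- Sigma[keep, keep, drop = FALSE] -
    S12 %*% solve(S22, t(S12))
  var_c[keep] <- diag(as.matrix(Scond))
  list(mean = mu_c, var = var_c)
}

# Minimize 0.5 x'Hx - g'x  s.t.  Aeq x = beq, G x >= h, by enumerating
# active subsets of the inequalities and solving each KKT system.
# Requires H positive definite on the equality null space (unique optimum).
qp_active_set_oracle <- function(H, g, Aeq = NULL, beq = NULL,
                                 G = NULL, h = NULL) {
  n <- length(g)
  m_in <- if (is.null(G)) 0L else nrow(G)
  m_eq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^m_in - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(m_in) - 1L)) > 0)
    C <- rbind(if (m_eq) Aeq, if (length(act)) G[act, , drop = FALSE])
    d <- c(if (m_eq) beq, if (length(act)) h[act])
    k <- NROW(C)
    K <- rbind(cbind(H, if (k) -t(C) else NULL),
               if (k) cbind(C, matrix(0, k, k)))
    rhs <- c(g, d)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    x <- sol[seq_len(n)]
    lam <- if (k > m_eq) sol[(n + m_eq + 1L):(n + k)] else numeric(0)
    ok_primal <- is.null(G) || all(G %*% x - h >= -1e-8)
    ok_dual <- all(lam >= -1e-8)
    if (ok_primal && ok_dual) {
      val <- 0.5 * drop(crossprod(x, H %*% x)) - sum(g * x)
      if (val < best_val - 1e-12) { best_val <- val; best <- x }
    }
  }
  best
}

# Random feasible weighted-LS problem with equality and inequality
# constraints, in the package's flux_problem container. Overdetermined
# target block keeps the Hessian positive definite (unique optimum).
random_lsei_problem <- function(n, seed) {
  set.seed(seed)
  k <- n + 2L
  A <- matrix(stats::rnorm(k * n), k, n)
  x_true <- stats::rnorm(n)
  b <- drop(A %*% x_true) + stats::rnorm(k, 0, 0.5)
  v <- stats::runif(k, 0.25, 4)
  m_eq <- sample(0:2, 1L)
  Aeq <- if (m_eq) matrix(stats::rnorm(m_eq * n), m_eq) else
    matrix(0, 0, n)
  beq <- drop(Aeq %*% x_true)
  m_in <- sample(2:6, 1L)
  G <- matrix(stats::rnorm(m_in * n), m_in)
  h <- drop(G %*% x_true) - stats::runif(m_in, 0.05, 1.5)
  ids <- sprintf("v%d", seq_len(n))
  colnames(A) <- ids; colnames(G) <- ids
  structure(list(E = Aeq, f = beq, G = G, h = h,
                 objective = stats::setNames(numeric(n), ids),
                 A = A, b = b, var = v, reactions = ids),
            class = "flux_problem")
}

# Shared small fixtures
chain_bn <- function() {
  dag <- validate_dag(rbind(c("X", "Y")))
  gbn(dag, intercept = c(X = 10, Y = 2), coef = list(Y = c(X = 0.5)),
      resid_var = c(X = 1, Y = 0.25))
}
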