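test_that("FBA finds the bottleneck optimum on a linear chain", {
  m <- stoich_model(c("A_ext", "A", "B_ext"), c(TRUE, FALSE, TRUE),
                    c("uptake", "conv"), c("A_ext -> A", "A -> B_ext"),
                    c(FALSE, FALSE), c(0, 0), c(5, 100))
  r <- fba_optimize(steady_state_system(m, c(conv = 1)))
  expect_equal(r$objective, 5)
  expect_equal(unname(r$flux), c(5, 5))
  # zero objective: value 0 at any feasible point
  r0 <- fba_optimize(steady_state_system(m), check_degenerate = FALSE)
  expect_equal(r0$objective, 0)
})

test_that("FBA reports infeasibility and unboundedness", {
  m <- stoich_model(c("A_ext", "A", "B_ext"), c(TRUE, FALSE, TRUE),
                    c("uptake", "conv"), c("A_ext -> A", "A -> B_ext"),
                    c(FALSE, FALSE), c(1, 0), c(5, 0))
  expect_error(fba_optimize(steady_state_system(m, c(conv = 1))),
               "infeasible")
  m2 <- stoich_model(c("A_ext", "A", "B_ext"), c(TRUE, FALSE, TRUE),
                     c("uptake", "conv"), c("A_ext -> A", "A -> B_ext"),
                     c(FALSE, FALSE), c(0, 0), c(Inf, Inf))
  expect_error(fba_optimize(steady_state_system(m2, c(conv = 1))),
               "unbounded")
})

test_that("FBA optimum dominates random feasible points", {
  tb <- toy_brain_model()
  pr <- steady_state_system(tb$model, tb$objective)
  opt <- suppressWarnings(fba_optimize(pr))
  rp <- reduce_polytope(pr)
  fs <- mirror_sample(rp, chain_config(iterations = 1300, burn_in = 300,
                                       chains = 1, seed = 12))
  vals <- drop(fs$samples %*% pr$objective)
  expect_gte(opt$objective, max(vals) - 1e-8)
  expect_equal(nrow(fs$samples), 1000L)
})

test_that("unconstrained least squares reproduces the targets exactly", {
  pr <- structure(list(E = matrix(0, 0, 2), f = numeric(0),
                       G = matrix(0, 0, 2), h = numeric(0),
                       objective = c(a = 0, b = 0),
                       A = diag(2), b = c(1, 2), var = c(1, 1),
                       reactions = c("a", "b")), class = "flux_problem")
  expect_equal(unname(lsei_solve(pr)), c(1, 2), tolerance = 1e-10)
})

test_that("the documented KKT example lands on the boundary optimum", {
  # min ||phi - (2,0)||^2  s.t.  phi1 + phi2 = 1, phi >= 0  ->  (1, 0)
  pr <- structure(list(E = matrix(1, 1, 2), f = 1, G = diag(2), h = c(0, 0),
                       objective = c(a = 0, b = 0),
                       A = diag(2), b = c(2, 0), var = c(1, 1),
                       reactions = c("a", "b")), class = "flux_problem")
  expect_equal(unname(lsei_solve(pr)), c(1, 0), tolerance = 1e-8)
})

test_that("inverse-variance weights pull the fit toward the heavier row", {
  # two conflicting targets for one free flux
  mk <- function(v) structure(
    list(E = matrix(0, 0, 1), f = numeric(0),
         G = matrix(0, 0, 1), h = numeric(0), objective = c(x = 0),
         A = matrix(c(1, 1), 2, 1), b = c(0, 1), var = v,
         reactions = "x"), class = "flux_problem")
  even <- lsei_solve(mk(c(1, 1)))
  heavy0 <- lsei_solve(mk(c(0.25, 1)))   # first row weight 4
  expect_equal(unname(even), 0.5, tolerance = 1e-10)
  expect_equal(unname(heavy0), 1 / 5, tolerance = 1e-10)  # (4*0+1*1)/5
})

test_that("constrained fits match the active-set QP oracle", {
  for (s in 1:30) {
    pr <- random_lsei_problem(n = sample(3:8, 1), seed = 9000 + s)
    fit <- lsei_solve(pr)
    W <- diag(1 / pr$var)
    H <- t(pr$A) %*% W %*% pr$A
    g <- drop(t(pr$A) %*% W %*% pr$b)
    orc <- qp_active_set_oracle(H, g,
                                Aeq = if (nrow(pr$E)) pr$E else NULL,
                                beq = if (nrow(pr$E)) pr$f else NULL,
                                G = pr$G, h = pr$h)
    expect_false(is.null(orc))
    expect_lt(max(abs(fit - orc)), 1e-6)
    # feasibility invariants
    if (nrow(pr$E)) expect_lt(max(abs(pr$E %*% fit - pr$f)), 1e-8)
    expect_gt(min(pr$G %*% fit - pr$h), -1e-8)
  }
})

test_that("lsei equals the unconstrained fit whenever that fit is feasible", {
  set.seed(31)
  A <- matrix(rnorm(12), 4, 3)
  xstar <- c(1, 2, 3)
  b <- drop(A %*% xstar)              # consistent: unconstrained optimum xstar
  pr <- structure(list(E = matrix(0, 0, 3), f = numeric(0),
                       G = diag(3), h = c(0, 0, 0),   # satisfied by xstar
                       objective = stats::setNames(numeric(3), c("a", "b", "c")),
                       A = A, b = b, var = rep(1, 4),
                       reactions = c("a", "b", "c")), class = "flux_problem")
  expect_equal(unname(lsei_solve(pr)), xstar, tolerance = 1e-8)
})

test_that("inconsistent equality systems are reported", {
  pr <- structure(list(E = rbind(c(1, 0), c(1, 0)), f = c(0, 1),
                       G = matrix(0, 0, 2), h = numeric(0),
                       objective = c(a = 0, b = 0),
                       A = diag(2), b = c(1, 1), var = c(1, 1),
                       reactions = c("a", "b")), class = "flux_problem")
  expect_error(lsei_solve(pr), "inconsistent")
})
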