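test_that("parentless nodes get sample mean and unbiased variance", {
  dag <- validate_dag(NULL, nodes = c("R", "S"))
  x <- cbind(R = c(9, 11), S = c(1, 3))
  bn <- fit_local_gaussians(x, dag)
  expect_equal(bn$local$R$intercept, 10)
  expect_equal(bn$local$R$resid_var, 2)
  expect_length(bn$local$R$coef, 0L)
})

test_that("local regressions match closed-form OLS normal equations", {
  set.seed(401)
  n <- 10000L
  X <- rnorm(n, 5, 2)
  Y <- 1 + 2 * X + rnorm(n, 0, 0.5)
  dat <- cbind(X = X, Y = Y)
  dag <- validate_dag(rbind(c("X", "Y")))
  bn <- fit_local_gaussians(dat, dag)
  # oracle: normal equations computed independently
  Xd <- cbind(1, X)
  beta <- solve(crossprod(Xd), crossprod(Xd, Y))
  expect_equal(bn$local$Y$intercept, beta[1L], tolerance = 1e-10)
  expect_equal(unname(bn$local$Y$coef[["X"]]), beta[2L], tolerance = 1e-10)
  expect_lt(abs(bn$local$Y$coef[["X"]] - 2), 0.02)
  # residual variance uses n - p - 1
  res <- Y - Xd %*% beta
  expect_equal(bn$local$Y$resid_var, sum(res^2) / (n - 2), tolerance = 1e-12)
})

test_that("degenerate designs are rejected with informative errors", {
  dag <- validate_dag(rbind(c("P1", "C"), c("P2", "C")))
  set.seed(7)
  p <- rnorm(30)
  x <- cbind(P1 = p, P2 = p, C = rnorm(30))
  expect_error(fit_local_gaussians(x, dag), "rank-deficient")
  x2 <- cbind(P1 = rnorm(30), P2 = rnorm(30), C = rep(1, 30))
  expect_error(fit_local_gaussians(x2, dag), "constant-valued")
  x3 <- x2[, c("P1", "P2")]
  expect_error(fit_local_gaussians(x3, dag), "absent")
  x4 <- cbind(P1 = rnorm(30), P2 = rnorm(30), C = rnorm(30))
  x4[1, 1] <- NA
  expect_error(fit_local_gaussians(x4, dag), "missing")
})

test_that("two-node joint Gaussian matches the closed form", {
  bn <- chain_bn()
  j <- to_joint_gaussian(bn)
  expect_equal(unname(j$mean), c(10, 7))
  expect_equal(j$cov["Y", "Y"], 0.5)
  expect_equal(j$cov["X", "Y"], 0.5)
  expect_equal(j$cov["X", "X"], 1)
})

test_that("zero residual variances give a deterministic (zero-cov) joint", {
  dag <- validate_dag(rbind(c("A", "B")))
  bn <- gbn(dag, intercept = c(A = 3, B = 1), coef = list(B = c(A = 0)),
            resid_var = c(A = 0, B = 0))
  j <- to_joint_gaussian(bn)
  expect_equal(unname(j$mean), c(3, 1))
  expect_true(all(j$cov == 0))
})

test_that("joint covariance matches ancestral-sampling moments", {
  fx <- random_gbn_dataset(nodes = 10, n_samples = 5, edge_prob = 0.3,
                           seed = 42)
  j <- to_joint_gaussian(fx$bn)
  set.seed(43)
  draws <- sample_gbn(fx$bn, 1e6)
  emp_mean <- colMeans(draws)
  emp_cov <- stats::cov(draws)
  sds <- sqrt(diag(j$cov))
  # mean: 3 standard errors of the mean
  expect_true(all(abs(emp_mean - j$mean) <= 3 * sds / sqrt(1e6) + 1e-12))
  # covariance entries: 3 SEs, normal approx se(cov_ij) ~ sqrt((s_ii s_jj + s_ij^2)/n)
  se_cov <- sqrt((outer(diag(j$cov), diag(j$cov)) + j$cov^2) / 1e6)
  expect_true(all(abs(emp_cov - j$cov) <= 3 * se_cov + 1e-12))
})

test_that("implied covariance is symmetric positive semi-definite", {
  for (s in 1:20) {
    fx <- random_gbn_dataset(nodes = sample(3:12, 1), n_samples = 5,
                             edge_prob = 0.4, seed = 500 + s)
    S <- to_joint_gaussian(fx$bn)$cov
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("fitted networks serialize to JSON and back unchanged", {
  fx <- random_gbn_dataset(nodes = 6, n_samples = 80, edge_prob = 0.4,
                           seed = 9)
  bn <- fit_local_gaussians(fx$x, fx$dag)
  path <- tempfile(fileext = ".json")
  write_gbn(bn, path)
  bn2 <- read_gbn(path)
  expect_equal(bn2$dag$nodes, bn$dag$nodes)
  for (v in bn$dag$nodes) {
    expect_equal(bn2$local[[v]]$intercept, bn$local[[v]]$intercept)
    expect_equal(bn2$local[[v]]$coef, bn$local[[v]]$coef)
    expect_equal(bn2$local[[v]]$resid_var, bn$local[[v]]$resid_var)
  }
})
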