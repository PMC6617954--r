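test_that("downstream evidence substitutes into the chain closed form", {
  bn <- chain_bn()
  pb <- propagate_evidence(bn, c(X = 12))
  expect_equal(pb$mean[["Y"]], 8)
  expect_equal(pb$var[["Y"]], 0.25)
  expect_equal(pb$mean[["X"]], 12)
  expect_equal(pb$var[["X"]], 0)
  expect_true(pb$is_evidence[["X"]])
})

test_that("upstream inference through a collider matches the partitioned formula", {
  dag <- validate_dag(rbind(c("X1", "Y"), c("X2", "Y")))
  bn <- gbn(dag, intercept = c(X1 = 0, X2 = 0, Y = 0),
            coef = list(Y = c(X1 = 1, X2 = 1)),
            resid_var = c(X1 = 1, X2 = 1, Y = 1))
  pb <- propagate_evidence(bn, c(Y = 3))
  expect_equal(pb$mean[["X1"]], 1)
  expect_equal(pb$var[["X1"]], 2 / 3, tolerance = 1e-12)
  expect_equal(pb$mean[["X2"]], 1)
})

test_that("nodes d-separated from the evidence keep their exact prior", {
  # A -> C <- B: evidence on A must leave B untouched (blocked collider)
  dag <- validate_dag(rbind(c("A", "C"), c("B", "C")))
  bn <- gbn(dag, intercept = c(A = 2, B = 5, C = 0),
            coef = list(C = c(A = 1, B = -1)),
            resid_var = c(A = 1, B = 2, C = 0.5))
  pb <- propagate_evidence(bn, c(A = 4))
  expect_identical(pb$mean[["B"]], pb$prior_mean[["B"]])
  expect_identical(pb$var[["B"]], pb$prior_var[["B"]])
})

test_that("sequential and joint absorption agree (order invariance)", {
  fx <- random_gbn_dataset(nodes = 8, n_samples = 5, edge_prob = 0.4,
                           seed = 77)
  ev <- c(G01 = 9.0, G05 = 10.5)
  p12 <- propagate_evidence(fx$bn, ev)
  p21 <- propagate_evidence(fx$bn, ev[c(2, 1)])
  expect_equal(p12$mean, p21$mean, tolerance = 1e-10)
  expect_equal(p12$var, p21$var, tolerance = 1e-10)
})

test_that("posterior variances never exceed prior marginal variances", {
  for (s in 1:25) {
    fx <- random_gbn_dataset(nodes = sample(4:12, 1), n_samples = 5,
                             edge_prob = 0.35, seed = 600 + s)
    ev_node <- sample(fx$dag$nodes, 1)
    pb <- propagate_evidence(fx$bn, stats::setNames(9, ev_node))
    expect_true(all(pb$var <= pb$prior_var + 1e-9))
  }
})

test_that("absorption matches block-partitioned conditioning on random nets", {
  for (s in 1:30) {
    fx <- random_gbn_dataset(nodes = sample(4:15, 1), n_samples = 5,
                             edge_prob = 0.35, seed = 700 + s)
    nodes <- fx$dag$nodes
    k <- sample(1:3, 1)
    ev_nodes <- sample(nodes, k)
    ev <- stats::setNames(runif(k, 8, 13), ev_nodes)
    pb <- propagate_evidence(fx$bn, ev)
    j <- to_joint_gaussian(fx$bn)
    orc <- condition_mvn_oracle(j$mean, j$cov, match(ev_nodes, nodes),
                                unname(ev))
    expect_lt(max(abs(pb$mean - orc$mean)), 1e-8)
    expect_lt(max(abs(pb$var - orc$var)), 1e-8)
  }
})

test_that("evidence guards reject unknown nodes and deterministic conflicts", {
  bn <- chain_bn()
  expect_error(propagate_evidence(bn, c(Z = 1)), "not in network")
  expect_error(propagate_evidence(bn, c(3, 4)), "named")
  expect_error(propagate_evidence(bn, c(X = Inf)), "finite")
  dag <- validate_dag(NULL, nodes = "D")
  det <- gbn(dag, intercept = c(D = 5), resid_var = c(D = 0))
  expect_error(propagate_evidence(det, c(D = 6)), "conflicts")
  # consistent evidence on a deterministic node is accepted
  pb <- propagate_evidence(det, c(D = 5))
  expect_equal(pb$mean[["D"]], 5)
})
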