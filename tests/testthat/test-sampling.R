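test_that("polytope reduction finds the affine parameterization", {
  # no equalities: full-dimensional, orthonormal N
  rp <- reduce_polytope(known_polytopes("interval"))
  expect_equal(dim(rp$N), c(1L, 1L))
  expect_equal(abs(rp$N[1, 1]), 1)
  expect_equal(rp$widths, 1)
  # one equality in 2D: line with direction (1,-1)/sqrt(2)
  pr <- structure(list(E = matrix(c(1, 1), 1, 2), f = 1,
                       G = diag(2), h = c(0, 0),
                       objective = c(a = 0, b = 0),
                       A = matrix(0, 0, 2), b = numeric(0),
                       var = numeric(0), reactions = c("a", "b")),
                  class = "flux_problem")
  rp2 <- reduce_polytope(pr)
  expect_equal(dim(rp2$N), c(2L, 1L))
  expect_equal(abs(sum(rp2$N[, 1] * c(1, -1) / sqrt(2))), 1,
               tolerance = 1e-10)
  # contradictory equalities
  bad <- pr
  bad$E <- rbind(c(1, 0), c(1, 0)); bad$f <- c(0, 1)
  expect_error(reduce_polytope(bad), "inconsistent|empty")
})

test_that("unbounded polytopes are refused for uniform sampling", {
  half <- structure(list(E = matrix(0, 0, 1), f = numeric(0),
                         G = matrix(1, 1, 1), h = 0,   # x >= 0 only
                         objective = c(x = 0), A = matrix(0, 0, 1),
                         b = numeric(0), var = numeric(0), reactions = "x"),
                    class = "flux_problem")
  expect_error(reduce_polytope(half), "unbounded")
})

test_that("one mirror reflection is an involution", {
  # reflecting a step across a hyperplane twice restores it
  G <- matrix(c(1, 2, -1, 0.5), 2, 2)
  for (i in 1:2) {
    g <- G[i, ]
    step <- c(0.7, -1.3)
    refl <- step - 2 * sum(g * step) / sum(g * g) * g
    back <- refl - 2 * sum(g * refl) / sum(g * g) * g
    expect_equal(back, step, tolerance = 1e-12)
  }
  # and the walker's path stays feasible across many reflections
  rp <- reduce_polytope(known_polytopes("interval"))
  z <- 0.5
  set.seed(5)
  for (k in 1:200) {
    z <- bnflux:::mirror_step(z, rnorm(1, 0, 2), rp$G, rp$h)
    expect_true(z >= -1e-12 && z <= 1 + 1e-12)
  }
})

test_that("uniform draws on the interval match analytic moments", {
  rp <- reduce_polytope(known_polytopes("interval"))
  fs <- mirror_sample(rp, chain_config(iterations = 11000, burn_in = 1000,
                                       chains = 1, seed = 2))
  s <- summarize_samples(fs)
  expect_lt(abs(s$mean - 0.5), 4 * s$se)
  expect_lt(abs(var(fs$samples[, 1]) - 1 / 12), 0.01)
  expect_true(all(fs$samples >= -1e-8 & fs$samples <= 1 + 1e-8))
})

test_that("the tied pair in the cut cube collapses to one coordinate", {
  rp <- reduce_polytope(known_polytopes("box_with_equality"))
  fs <- mirror_sample(rp, chain_config(iterations = 6000, burn_in = 1000,
                                       chains = 2, seed = 8))
  expect_equal(cor(fs$samples[, "v1"], fs$samples[, "v2"]), 1)
  s <- summarize_samples(fs)
  expect_true(all(abs(s$mean - 0.5) < 4 * s$se))
})

test_that("sampling is deterministic under a fixed master seed", {
  rp <- reduce_polytope(known_polytopes("simplex"))
  cfg <- chain_config(iterations = 1500, burn_in = 500, chains = 2, seed = 99)
  f1 <- mirror_sample(rp, cfg)
  f2 <- mirror_sample(rp, cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- mirror_sample(rp, chain_config(iterations = 1500, burn_in = 500,
                                       chains = 2, seed = 100))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("summaries report means, batch-mean SEs and quantiles", {
  fs <- structure(list(samples = cbind(flat = rep(2, 500),
                                       ramp = seq(0, 1, length.out = 500)),
                       chain = rep(1L, 500),
                       reactions = c("flat", "ramp")),
                  class = "flux_samples")
  s <- summarize_samples(fs)
  expect_equal(s$mean[s$reaction == "flat"], 2)
  expect_equal(s$se[s$reaction == "flat"], 0)
  expect_equal(s$q50[s$reaction == "ramp"], 0.5, tolerance = 0.01)
  expect_error(summarize_samples(structure(
    list(samples = matrix(0, 0, 1), chain = integer(0), reactions = "x"),
    class = "flux_samples")), "empty")
})
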