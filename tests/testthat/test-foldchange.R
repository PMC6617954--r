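make_fitted_chain <- function(n = 400L, seed = 21L) {
  set.seed(seed)
  TF <- rnorm(n, 10, 1)
  EZ <- 2 + 0.5 * TF + rnorm(n, 0, 0.5)
  x <- cbind(TF = TF, EZ = EZ)
  dag <- validate_dag(rbind(c("TF", "EZ")))
  list(x = x, bn = fit_local_gaussians(x, dag))
}

test_that("evidence at the baseline mean yields unit fold changes", {
  fc <- make_fitted_chain()
  ev <- c(TF = mean(fc$x[, "TF"]))
  tab <- compute_fold_changes(fc$bn, fc$x, ev)
  expect_lt(max(abs(tab$fold_change - 1)), 1e-8)
})

test_that("chain fold change equals the propagated-mean ratio", {
  # exact parameters rather than a fit: X mean 10, Y = 2 + 0.5 X
  bn <- chain_bn()
  x <- cbind(X = c(10, 10), Y = c(7, 7))  # baselines equal the BN means
  tab <- compute_fold_changes(bn, x, c(X = 12), genes = "Y")
  expect_equal(tab$fold_change, 8 / 7, tolerance = 1e-12)
})

test_that("nonpositive baseline means are rejected by name", {
  bn <- chain_bn()
  x <- cbind(X = c(10, 10), Y = c(-1, 1))  # Y baseline mean 0
  expect_error(compute_fold_changes(bn, x, c(X = 12), genes = "Y"), "Y")
})

test_that("reaction aggregation averages gene fold changes", {
  fcs <- data.frame(gene = c("g1", "g2", "g3"),
                    baseline = 1, perturbed = 1,
                    fold_change = c(1.2, 1.4, 0.9), is_evidence = FALSE)
  map <- gene_reaction_map(list(R1 = c("g1", "g2"), R2 = "g3"))
  rfc <- aggregate_reaction_fold_changes(fcs, map)
  expect_equal(unname(rfc["R1"]), 1.3)
  expect_equal(unname(rfc["R2"]), 0.9)
  # permutation invariance in gene order
  map2 <- gene_reaction_map(list(R1 = c("g2", "g1"), R2 = "g3"))
  expect_equal(aggregate_reaction_fold_changes(fcs, map2), rfc)
  # neutral input stays neutral
  fcs$fold_change <- 1
  expect_true(all(aggregate_reaction_fold_changes(fcs, map) == 1))
  # missing gene errors
  map3 <- gene_reaction_map(list(R1 = c("g1", "gX")))
  expect_error(aggregate_reaction_fold_changes(fcs, map3), "gX")
})

test_that("modifier rules divide the target by the modifier fold change", {
  fcs <- data.frame(gene = c("PDHA", "PDK"), baseline = 1, perturbed = 1,
                    fold_change = c(1.5, 2.0), is_evidence = FALSE)
  map <- gene_reaction_map(list(R_PDH = "PDHA"),
                           rules = data.frame(reaction = "R_PDH",
                                              modifier = "PDK"))
  rfc <- aggregate_reaction_fold_changes(fcs, map)
  adj <- apply_modifier_rules(rfc, fcs, map)
  expect_equal(unname(adj["R_PDH"]), 0.75)
  # alpha = 1 leaves the target unchanged
  fcs$fold_change <- c(1.5, 1)
  adj1 <- apply_modifier_rules(rfc, fcs, map)
  expect_equal(adj1, rfc)
  # alpha = 0 is rejected
  fcs$fold_change <- c(1.5, 0)
  expect_error(apply_modifier_rules(rfc, fcs, map), "nonpositive")
})

test_that("target rows scale baselines and carry row variances", {
  baseline <- c(R1 = 2, R2 = -1, R3 = 0.5)
  rfc <- c(R1 = 1.3, R3 = 1)
  tg <- build_target_vector(baseline, rfc, names(baseline))
  expect_equal(dim(tg$A), c(2L, 3L))
  expect_equal(unname(tg$A["R1", ]), c(1, 0, 0))
  expect_equal(unname(tg$A["R3", ]), c(0, 0, 1))
  expect_equal(tg$b, c(2.6, 0.5))
  expect_equal(tg$var, (0.1 * abs(c(2, 0.5)))^2)
  # explicit standard deviations override the relative default
  tg2 <- build_target_vector(baseline, rfc, names(baseline),
                             sd = c(R1 = 1, R3 = 2))
  expect_equal(tg2$var, c(1, 4))
  # hand-written three-constraint system
  rfc3 <- c(R1 = 2, R2 = 1, R3 = 4)
  tg3 <- build_target_vector(baseline, rfc3, names(baseline))
  expect_equal(tg3$A, diag(3), ignore_attr = TRUE)
  expect_equal(tg3$b, c(4, -1, 2))
  expect_error(build_target_vector(baseline, c(RX = 1), names(baseline)),
               "absent")
})
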