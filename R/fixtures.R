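#' Random Gaussian BN with ancestral-sampled expression data
#'
#' Draws a random DAG (uniform topological order, independent Bernoulli
#' edges), random local-Gaussian parameters in the given ranges, and an
#' expression matrix sampled ancestrally from the ground-truth network.
#' Intercepts are chosen so marginal means sit on a microarray-like log2
#' intensity scale (roots near `root_mean`). Used for parameter-recovery
#' and inference-oracle testing; the generator does not emulate probe- or
#' batch-level artifacts of real microarray data.
#'
#' @param nodes number of genes (>= 2)
#' @param n_samples rows of the expression matrix
#' @param edge_prob probability of each forward edge (default 0.15)
#' @param slope_range range of regression slopes; a sign is drawn at random
#'   unless `positive_slopes` (default c(0.3, 0.8))
#' @param resid_var_range range of residual variances (default c(0.1, 0.4))
#' @param root_mean mean intensity of root nodes (default 9.5)
#' @param positive_slopes if TRUE all slopes are positive
#' @param seed RNG seed (fixture stream is isolated via its own seed)
#' @return list with `dag`, `bn` (ground truth `gbn`), `x` (expression
#'   matrix)
#' @export
random_gbn_dataset <- function(nodes, n_samples, edge_prob = 0.15,
                               slope_range = c(0.3, 0.8),
                               resid_var_range = c(0.1, 0.4),
                               root_mean = 9.5, positive_slopes = FALSE,
                               seed = 1L) {
  stopifnot(nodes >= 2)
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(nodes))
  ord <- sample(ids)                       # uniform topological order
  edges <- NULL
  for (i in seq_len(nodes - 1L)) for (j in seq.int(i + 1L, nodes)) {
    if (stats::runif(1) < edge_prob) edges <- rbind(edges, c(ord[i], ord[j]))
  }
  dag <- validate_dag(edges, nodes = ids)
  coef <- list(); intercept <- numeric(0); resid_var <- numeric(0)
  for (v in ids) {
    pa <- dag$parents[[v]]
    sl <- stats::runif(length(pa), slope_range[1L], slope_range[2L])
    if (!positive_slopes) sl <- sl * sample(c(-1, 1), length(pa), replace = TRUE)
    coef[[v]] <- stats::setNames(sl, pa)
    # anchor marginal means near root_mean regardless of depth
    intercept[[v]] <- if (length(pa)) stats::runif(1, -1, 1) else
      root_mean + stats::runif(1, -0.5, 0.5)
    resid_var[[v]] <- stats::runif(1, resid_var_range[1L], resid_var_range[2L])
  }
  bn <- gbn(dag, intercept = intercept, coef = coef, resid_var = resid_var)
  x <- sample_gbn(bn, n_samples)
  rownames(x) <- sprintf("S%05d", seq_len(n_samples))
  list(dag = dag, bn = bn, x = x)
}

#' Miniature brain-like metabolic model
#'
#' A fixed integer-coefficient toy network in the spirit of a core brain
#' energy-metabolism reconstruction: glucose uptake feeds a two-step
#' glycolysis-like branch producing ATP and pyruvate; pyruvate is either
#' exported as lactate (anaerobic, reversible: brain tissue can also
#' consume lactate) or oxidized by a lumped pyruvate-dehydrogenase/TCA/
#' oxidative-phosphorylation reaction with a much higher ATP yield but an
#' oxygen requirement; an ATP drain closes the system. Glucose and oxygen
#' uptakes are capped so the feasible flux polytope is bounded.
#'
#' Reactions: `R_GLCup` (glc_e -> glc, ub 10), `R_HK` (glc -> g6p),
#' `R_PYK` (g6p -> 2 pyr + 2 atp), `R_LDH` (pyr <-> lac_e, in [-5, 20]),
#' `R_O2up` (o2_e -> o2, ub 15), `R_PDH` (pyr + 3 o2 -> 3 co2_e + 15 atp),
#' `R_ATPase` (atp ->).
#'
#' @return list with `model` (a `stoich_model`) and `objective` (named
#'   weights: net ATP production = the drain flux `R_ATPase`)
#' @export
toy_brain_model <- function() {
  model <- stoich_model(
    metabolite_ids = c("glc_e", "o2_e", "lac_e", "co2_e",
                       "glc", "g6p", "pyr", "o2", "atp"),
    external = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    reaction_ids = c("R_GLCup", "R_HK", "R_PYK", "R_LDH", "R_O2up",
                     "R_PDH", "R_ATPase"),
    equations = c("glc_e -> glc",
                  "glc -> g6p",
                  "g6p -> 2 pyr + 2 atp",
                  "pyr <-> lac_e",
                  "o2_e -> o2",
                  "pyr + 3 o2 -> 3 co2_e + 15 atp",
                  "atp ->"),
    reversible = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    lb = c(0, 0, 0, -5, 0, 0, 0),
    ub = c(10, 20, 20, 20, 15, 10, 200)
  )
  list(model = model, objective = c(R_ATPase = 1))
}

#' Regulated toy system: transcription factor, enzymes, metabolic coupling
#'
#' Builds the full miniature analog of a hypoxia-style regulatory program
#' driving glycolysis: one transcription-factor gene (`TF`) with positive
#' regression slopes onto enzyme transcripts mapped to reactions of
#' [toy_brain_model()], plus one kinase-like modifier gene (`PDK`) whose
#' predicted fold change alpha divides the fold change of the
#' pyruvate-dehydrogenase reaction (post-translational inhibition). The TF
#' slope onto the directly-regulated dehydrogenase transcript (0.6)
#' exceeds the slope onto the kinase (0.2), so the effective response of
#' the aerobic branch to TF activation remains positive — together with
#' the all-positive couplings this makes the ATP objective a nondecreasing
#' function of the TF evidence value, the ground truth consumed by the
#' sweep tests.
#'
#' The expression data are ancestral draws from the ground-truth network at
#' a microarray-like scale (TF marginal mean 9.5, matching a basal
#' transcription-factor level; evidence sweeps typically span 8 to 13).
#' The baseline flux vector is a hand-chosen strictly interior feasible
#' point of the toy polytope, standing in for a basal-condition flux fit.
#'
#' @param n_samples samples per condition (default 200)
#' @param conditions character vector of condition labels (default
#'   `c("control", "disease")`; the disease condition reuses the same
#'   network with slopes damped by `disease_damping`)
#' @param disease_damping multiplier on regulatory slopes in the second and
#'   later conditions (default 0.4, emulating a blunted regulatory program)
#' @param seed RNG seed
#' @return list with `dag`, `bn` (list of ground-truth `gbn` per condition),
#'   `x` (stacked expression matrix), `condition` (label per row), `map`
#'   (a `gene_reaction_map` with the kinase rule), `model`, `objective`,
#'   `baseline_flux` (named interior feasible flux vector), `tf` (= "TF")
#' @export
regulated_toy_system <- function(n_samples = 200L,
                                 conditions = c("control", "disease"),
                                 disease_damping = 0.4, seed = 1L) {
  set.seed(seed)
  enzymes <- c("HK1", "HK2", "PYK", "LDHA", "PDHA", "PDK")
  ids <- c("TF", enzymes)
  edges <- cbind("TF", enzymes)
  dag <- validate_dag(edges, nodes = ids)
  slopes <- c(HK1 = 0.45, HK2 = 0.35, PYK = 0.5, LDHA = 0.55,
              PDHA = 0.6, PDK = 0.2)
  resid_var <- c(TF = 0.25, HK1 = 0.15, HK2 = 0.15, PYK = 0.15,
                 LDHA = 0.15, PDHA = 0.15, PDK = 0.15)
  bns <- list(); xs <- list(); cond <- character(0)
  for (k in seq_along(conditions)) {
    damp <- if (k == 1L) 1 else disease_damping
    coef <- lapply(stats::setNames(enzymes, enzymes), function(e)
      stats::setNames(slopes[[e]] * damp, "TF"))
    # intercepts put every enzyme's marginal mean near 9.5 at TF = 9.5
    intercept <- c(TF = 9.5,
                   vapply(enzymes, function(e) 9.5 - slopes[[e]] * damp * 9.5,
                          numeric(1L)))
    bn <- gbn(dag, intercept = intercept, coef = coef, resid_var = resid_var)
    x <- sample_gbn(bn, n_samples)
    rownames(x) <- sprintf("%s_%04d", conditions[k], seq_len(n_samples))
    bns[[conditions[k]]] <- bn
    xs[[k]] <- x
    cond <- c(cond, rep(conditions[k], n_samples))
  }
  tb <- toy_brain_model()
  map <- gene_reaction_map(
    genes = list(R_HK = c("HK1", "HK2"), R_PYK = "PYK",
                 R_LDH = "LDHA", R_PDH = "PDHA"),
    rules = data.frame(reaction = "R_PDH", modifier = "PDK",
                       stringsAsFactors = FALSE)
  )
  baseline_flux <- c(R_GLCup = 4, R_HK = 4, R_PYK = 4, R_LDH = 5,
                     R_O2up = 9, R_PDH = 3, R_ATPase = 53)
  list(dag = dag, bn = bns, x = do.call(rbind, xs), condition = cond,
       map = map, model = tb$model, objective = tb$objective,
       baseline_flux = baseline_flux, tf = "TF")
}

#' Named reference polytopes with analytic moments
#'
#' Small flux problems whose uniform distribution has closed-form moments,
#' used to validate the mirror sampler: `"interval"` (uniform on [0, 1]:
#' mean 1/2, variance 1/12), `"simplex"` (the standard 2-simplex in 3
#' coordinates: each coordinate is marginally Beta(1, 2) with mean 1/3 and
#' variance 1/18), and `"box_with_equality"` (the unit cube cut by
#' `Phi_1 = Phi_2`: means 1/2, perfect correlation of the tied pair).
#'
#' @param name one of `"interval"`, `"simplex"`, `"box_with_equality"`
#' @return a `flux_problem` with attribute `moments` (list with `mean` and
#'   `var` per coordinate)
#' @export
known_polytopes <- function(name = c("interval", "simplex",
                                     "box_with_equality")) {
  name <- match.arg(name)
  fp <- function(E, f, G, h, ids) {
    structure(list(E = E, f = f, G = G, h = h,
                   objective = stats::setNames(numeric(length(ids)), ids),
                   A = matrix(0, 0, length(ids)), b = numeric(0),
                   var = numeric(0), reactions = ids),
              class = "flux_problem")
  }
  if (name == "interval") {
    pr <- fp(E = matrix(0, 0, 1), f = numeric(0),
             G = rbind(1, -1), h = c(0, -1), ids = "v1")
    attr(pr, "moments") <- list(mean = c(v1 = 0.5), var = c(v1 = 1 / 12))
  } else if (name == "simplex") {
    ids <- c("v1", "v2", "v3")
    pr <- fp(E = matrix(1, 1, 3), f = 1,
             G = diag(3), h = numeric(3), ids = ids)
    attr(pr, "moments") <- list(
      mean = stats::setNames(rep(1 / 3, 3), ids),
      var = stats::setNames(rep(1 / 18, 3), ids))
  } else {
    ids <- c("v1", "v2", "v3")
    pr <- fp(E = matrix(c(1, -1, 0), 1, 3), f = 0,
             G = rbind(diag(3), -diag(3)), h = c(rep(0, 3), rep(-1, 3)),
             ids = ids)
    attr(pr, "moments") <- list(
      mean = stats::setNames(rep(0.5, 3), ids),
      var = stats::setNames(c(1 / 12, 1 / 12, 1 / 12), ids))
  }
  pr
}
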