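#' MCMC chain configuration
#'
#' Defaults follow the study protocol this package implements: 100,000
#' iterations per chain with the first 2,000 discarded as burn-in, and four
#' chains so that the Gelman-Rubin diagnostic is defined.
#'
#' @param iterations iterations per chain (default 1e5)
#' @param burn_in discarded leading draws (default 2000; must be < iterations)
#' @param chains number of chains (default 4)
#' @param jump_scale proposal standard deviation as a fraction of the
#'   per-dimension feasible width (default 0.5); the width is measured by
#'   axis-aligned LP extents in the reduced coordinates
#' @param seed master seed; chain i uses seed + i
#' @param thin keep every `thin`-th post-burn-in draw (default 1)
#' @return a `chain_config` list
#' @export
chain_config <- function(iterations = 100000L, burn_in = 2000L, chains = 4L,
                         jump_scale = 0.5, seed = 1L, thin = 1L) {
  stopifnot(iterations > 0, burn_in >= 0, burn_in < iterations,
            chains >= 1, jump_scale > 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains),
                 jump_scale = jump_scale,
                 seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "chain_config")
}

#' Reduce a flux problem to its inequality-constrained coordinates
#'
#' The equality constraints confine the feasible set to an affine subspace;
#' sampling happens in coordinates z on that subspace via
#' `Phi = Phi0 + N z` with N an orthonormal null-space basis of the
#' equality matrix. Inequalities `G Phi >= h` become `(G N) z >= h - G Phi0`.
#' The anchor `Phi0` is the least-squares fit when target rows are present,
#' otherwise a Chebyshev-center LP solution; boundedness of every reduced
#' direction is verified by LP and violations are an error (a uniform
#' distribution on an unbounded polytope is undefined).
#'
#' @param problem a `flux_problem`
#' @param phi0 optional anchor flux vector (must satisfy the equalities)
#' @return object of class `reduced_polytope`: `phi0`, `N`, `G` and `h`
#'   (reduced inequalities), `center` (Chebyshev center in z), `widths`
#'   (per-dimension extent), `reactions`
#' @export
reduce_polytope <- function(problem, phi0 = NULL) {
  stopifnot(inherits(problem, "flux_problem"))
  n <- length(problem$reactions)
  if (nrow(problem$E) > 0L) {
    base <- drop(MASS::ginv(problem$E) %*% problem$f)
    if (max(abs(problem$E %*% base - problem$f)) >
        1e-8 * max(1, max(abs(problem$f))))
      stop("equality constraints are inconsistent; feasible set is empty")
    N <- MASS::Null(t(problem$E))
    if (length(N) == 0L) N <- matrix(0, n, 0)
  } else {
    base <- numeric(n)
    N <- diag(n)
  }
  if (is.null(phi0)) {
    phi0 <- base
  } else {
    if (nrow(problem$E) &&
        max(abs(problem$E %*% phi0 - problem$f)) > 1e-6)
      stop("supplied anchor violates the equality constraints")
    phi0 <- drop(phi0)
  }
  d <- ncol(N)
  if (d == 0L) {
    # zero-dimensional polytope: single point
    if (nrow(problem$G) && any(problem$G %*% phi0 - problem$h < -1e-8))
      stop("feasible set is empty (equalities pin an infeasible point)")
    return(structure(list(phi0 = phi0, N = N,
                          G = matrix(0, 0, 0), h = numeric(0),
                          center = numeric(0), widths = numeric(0),
                          reactions = problem$reactions),
                     class = "reduced_polytope"))
  }
  if (nrow(problem$G) == 0L)
    stop("polytope is unbounded: no inequality constraints restrict the ",
         "free directions; a uniform target is undefined")
  Gz <- problem$G %*% N
  offset <- drop(phi0) - base
  z_off <- drop(crossprod(N, offset))   # phi0 = base + N z_off (N orthonormal)
  hz <- drop(problem$h - problem$G %*% base)

  # Chebyshev center: max r s.t. Gz z - r*||row|| >= hz
  norms <- sqrt(rowSums(Gz^2))
  cheb <- solve_lp(c(rep(0, d), 1),
                   G = cbind(Gz, -norms), h = hz, maximize = TRUE)
  if (cheb$status == "infeasible" ||
      (cheb$status == "optimal" && cheb$value < 0))
    stop("feasible set is empty")
  if (cheb$status == "unbounded")
    stop("polytope is unbounded (inscribed-ball radius diverges); ",
         "a uniform target is undefined")
  center <- cheb$x[seq_len(d)]

  # axis-aligned extents: verify boundedness, estimate widths
  widths <- numeric(d)
  for (k in seq_len(d)) {
    ek <- numeric(d); ek[k] <- 1
    lo <- solve_lp(ek, G = Gz, h = hz, maximize = FALSE)
    hi <- solve_lp(ek, G = Gz, h = hz, maximize = TRUE)
    if (lo$status == "unbounded" || hi$status == "unbounded")
      stop("polytope is unbounded along a free flux direction; ",
           "a uniform target is undefined")
    widths[k] <- hi$value - lo$value
  }

  # soft target rows become a Gaussian log-likelihood over the polytope
  Aw_z <- NULL; rw0 <- NULL
  if (nrow(problem$A) > 0L) {
    sw <- 1 / sqrt(problem$var)
    Aw <- problem$A * sw
    Aw_z <- Aw %*% N
    rw0 <- drop(Aw %*% base) - problem$b * sw
  }

  structure(list(phi0 = base, N = N, G = Gz, h = hz,
                 center = center, z_anchor = z_off, widths = widths,
                 Aw = Aw_z, rw0 = rw0,
                 reactions = problem$reactions),
            class = "reduced_polytope")
}

# One mirror move: walk from feasible z along step d, reflecting specularly
# off every inequality hyperplane hit on the way. G z >= h.
# Returns new point or NULL if max_reflect exceeded.
mirror_step <- function(z, step, G, h, max_reflect = 1000L) {
  refl <- 0L
  Gn2 <- rowSums(G^2)
  repeat {
    Gz <- drop(G %*% z)
    Gd <- drop(G %*% step)
    # fraction of the step at which each constraint is hit (only those we
    # are moving toward, Gd < 0)
    toward <- Gd < -1e-14
    if (!any(toward)) return(z + step)
    alpha <- rep(Inf, length(h))
    alpha[toward] <- (h[toward] - Gz[toward]) / Gd[toward]
    alpha[alpha < 0] <- Inf          # already past (numerically), ignore
    j <- which.min(alpha)
    a <- alpha[j]
    if (a >= 1) return(z + step)
    refl <- refl + 1L
    if (refl > max_reflect) return(NULL)
    z <- z + a * step
    rest <- (1 - a) * step
    gj <- G[j, ]
    step <- rest - 2 * (sum(gj * rest) / Gn2[j]) * gj
  }
}

#' Sample the flux polytope by mirror MCMC
#'
#' Random-walk Markov chain whose Gaussian proposals are reflected
#' specularly off the inequality hyperplanes until the candidate lies
#' inside the polytope; reflection preserves proposal symmetry. With no
#' soft target rows every reflected proposal is accepted and the
#' stationary distribution is uniform over the polytope. When the flux
#' problem carries approximate rows `A Phi ~ b` with error variances, the
#' target is the corresponding Gaussian likelihood restricted to the
#' polytope and reflected proposals are accepted by the Metropolis rule.
#' Chains start at the anchor point (nudged toward the Chebyshev center
#' when it lies on the boundary) and are run independently with per-chain
#' seeds `seed + i`.
#'
#' @param rp a `reduced_polytope`
#' @param config a [chain_config()]
#' @param start optional starting point in flux coordinates (defaults to the
#'   anchor used in [reduce_polytope()])
#' @return object of class `flux_samples`: `samples` (draws x fluxes matrix,
#'   post-burn-in, all chains stacked), `chain` (chain id per draw),
#'   `z` (reduced-coordinate draws), `config`, `reactions`, `accept_rate`
#' @export
mirror_sample <- function(rp, config = chain_config(), start = NULL) {
  stopifnot(inherits(rp, "reduced_polytope"), inherits(config, "chain_config"))
  d <- length(rp$center)
  if (d == 0L) {
    keep <- max(config$iterations - config$burn_in, 1L) * config$chains
    phi <- matrix(rep(rp$phi0, each = keep), keep,
                  dimnames = list(NULL, rp$reactions))
    return(structure(list(samples = phi,
                          chain = rep(seq_len(config$chains),
                                      each = keep / config$chains),
                          z = matrix(0, keep, 0), config = config,
                          reactions = rp$reactions, accept_rate = 1),
                     class = "flux_samples"))
  }
  z0 <- if (is.null(start)) {
    if (!is.null(rp$z_anchor)) rp$z_anchor else rp$center
  } else {
    drop(crossprod(rp$N, drop(start) - rp$phi0))
  }
  slack <- drop(rp$G %*% z0) - rp$h
  if (any(slack < 1e-9)) {
    # on (or numerically at) the boundary: pull toward the Chebyshev center
    diam <- max(rp$widths)
    dir <- rp$center - z0
    nd <- sqrt(sum(dir^2))
    z0 <- if (nd < 1e-12) rp$center else z0 + min(1, 1e-6 * diam / nd) * dir
    if (any(drop(rp$G %*% z0) - rp$h < 0)) z0 <- rp$center
  }
  sigma <- config$jump_scale * rp$widths
  sigma[rp$widths <= 1e-12] <- 0   # flat directions: stay on the face

  weighted <- !is.null(rp$Aw) && nrow(rp$Aw) > 0L
  loglik <- function(z) {
    r <- drop(rp$Aw %*% z) + rp$rw0
    -0.5 * sum(r * r)
  }
  if (weighted) {
    # scale proposals to the likelihood's curvature where it is informative,
    # never beyond the width-based uniform default
    Hz <- crossprod(rp$Aw)
    ev <- eigen(Hz, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * max(ev, 1)) {
      sd_post <- sqrt(diag(solve(Hz)))
      sigma <- pmin(sigma, 2.4 / sqrt(d) * sd_post)
    }
  }

  keep_per <- (config$iterations - config$burn_in) %/% config$thin
  total <- keep_per * config$chains
  Z <- matrix(NA_real_, total, d)
  chain_id <- integer(total)
  rejected <- 0L
  reflect_fail <- 0L
  row <- 0L
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch)
    z <- z0
    ll <- if (weighted) loglik(z) else 0
    kept <- 0L
    for (it in seq_len(config$iterations)) {
      step <- stats::rnorm(d, 0, sigma)
      znew <- mirror_step(z, step, rp$G, rp$h)
      if (is.null(znew)) {
        reflect_fail <- reflect_fail + 1L
        if (reflect_fail == 1L)
          warning("mirror reflection limit exceeded; proposal rejected ",
                  "(consider a smaller jump_scale)")
      } else if (!weighted) {
        z <- znew
      } else {
        llnew <- loglik(znew)
        if (log(stats::runif(1)) < llnew - ll) {
          z <- znew; ll <- llnew
        } else rejected <- rejected + 1L
      }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L &&
          kept < keep_per) {
        kept <- kept + 1L; row <- row + 1L
        Z[row, ] <- z
        chain_id[row] <- ch
      }
    }
  }
  rejected <- rejected + reflect_fail
  phi <- sweep(Z %*% t(rp$N), 2L, rp$phi0, `+`)
  colnames(phi) <- rp$reactions
  structure(list(samples = phi, chain = chain_id, z = Z, config = config,
                 reactions = rp$reactions,
                 accept_rate = 1 - rejected /
                   (config$iterations * config$chains)),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("Flux sample set:", nrow(x$samples), "draws x",
      ncol(x$samples), "fluxes (", max(x$chain), "chain(s) )\n")
  invisible(x)
}

#' Summarize flux samples
#'
#' Per-flux posterior mean, Monte-Carlo standard error of the mean (batch
#' means, within-chain, averaged over chains) and 2.5/50/97.5% quantiles.
#'
#' @param fs a `flux_samples`
#' @param reactions subset of reaction ids (default: all)
#' @return data frame with columns `reaction`, `mean`, `se`, `q025`, `q50`,
#'   `q975`
#' @export
summarize_samples <- function(fs, reactions = NULL) {
  stopifnot(inherits(fs, "flux_samples"))
  if (nrow(fs$samples) == 0L) stop("empty sample set")
  if (is.null(reactions)) reactions <- fs$reactions
  X <- fs$samples[, reactions, drop = FALSE]
  data.frame(
    reaction = reactions,
    mean = colMeans(X),
    se = vapply(reactions, function(r)
      mcmc_se(X[, r], fs$chain), numeric(1L)),
    q025 = apply(X, 2L, stats::quantile, 0.025, names = FALSE),
    q50 = apply(X, 2L, stats::quantile, 0.50, names = FALSE),
    q975 = apply(X, 2L, stats::quantile, 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Batch-means MC standard error of the overall mean, respecting chains:
# within each chain, split into ~sqrt(n) batches; pooled across chains.
mcmc_se <- function(x, chain) {
  per_chain_var <- tapply(seq_along(x), chain, function(idx) {
    xi <- x[idx]
    n <- length(xi)
    if (n < 4L || stats::var(xi) == 0) return(0)
    nb <- max(2L, floor(sqrt(n)))
    bs <- floor(n / nb)
    bm <- colMeans(matrix(xi[seq_len(nb * bs)], bs, nb))
    stats::var(bm) * bs / n          # var of this chain's mean
  })
  m <- length(per_chain_var)
  sqrt(mean(unlist(per_chain_var)) / m)
}

#' Write flux samples to TSV
#' @param fs a `flux_samples`
#' @param path output path
#' @export
write_samples <- function(fs, path) {
  out <- data.frame(draw = seq_len(nrow(fs$samples)), chain = fs$chain,
                    fs$samples, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
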