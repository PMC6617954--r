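---
title: "Methods: coupling a Gaussian regulatory network to constraint-based flux estimation"
author: "bnflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling a Gaussian regulatory network to constraint-based flux estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnflux)
```

## Overview

`bnflux` couples two model classes that are usually studied separately:

1. a **Gaussian Bayesian network** (BN) over transcript abundances of a
   signaling/regulatory pathway, parameterized from expression data; and
2. a **constraint-based model of metabolism** at steady state, whose
   feasible flux set is a convex polytope.

The bridge is probabilistic: clamping a transcription factor's abundance
to a hypothetical value ("evidence") and propagating that evidence through
the BN yields predicted posterior means for every enzyme transcript that
is d-connected to the evidence. The ratio of each posterior mean to the
gene's observed baseline mean is a predicted **fold change**; fold changes
are aggregated onto reactions and embedded as soft targets in a
least-squares flux-fitting problem whose solution space is then explored by
Markov chain Monte Carlo. Sweeping the evidence value over a grid, per
condition (e.g. healthy vs. diseased expression data), produces response
curves of any linear flux objective — in the intended application, net ATP
production of brain energy metabolism.

## The Gaussian Bayesian network

The pathway structure is a DAG $G$ over genes $X_1,\dots,X_n$. The joint
density factorizes into local conditionals,
$P(X_1,\dots,X_n) = \prod_i P(X_i \mid \mathrm{pa}(X_i), \Theta_i)$,
and each local model is linear Gaussian:

$$X_i \mid \mathrm{pa}(X_i) \sim \mathcal N\!\Big(\beta_{0i} + \sum_{j \in \mathrm{pa}(i)} \beta_{ij} X_j,\ \sigma_i^2\Big).$$

`fit_local_gaussians()` estimates $(\beta_{0i}, \beta_{ij}, \sigma_i^2)$
by ordinary least squares of each node on its parents. The residual
variance uses the unbiased denominator $n - p - 1$ (the convention of
`lm()`); parentless nodes receive their sample mean and unbiased sample
variance. Expression values are used on the scale provided — for
microarray data typically log2 intensity in the 8–13 range — with no
antilog; `compute_fold_changes(antilog = TRUE)` is available when ratios
of linear-scale intensities are wanted instead.

Assumptions worth keeping in mind: linearity of each regulatory effect,
homoscedastic Gaussian noise, acyclicity (no feedback), and complete data
(missing values and unmeasured pathway genes are errors, not imputation
targets).

### Exact inference

A linear Gaussian BN is equivalent to one multivariate normal
$\mathcal N(\mu, \Sigma)$ with $\mu = (I-B)^{-1}\beta_0$ and
$\Sigma = (I-B)^{-1} D (I-B)^{-\top}$, where $B$ holds the parent slopes
and $D = \mathrm{diag}(\sigma_i^2)$ (`to_joint_gaussian()`). Point
evidence $X_e = v$ is absorbed by exact Gaussian conditioning.
`propagate_evidence()` absorbs the evidence items sequentially with the
rank-one update

$$\mu' = \mu + \frac{\Sigma_{\cdot e}}{\Sigma_{ee}}(v - \mu_e), \qquad
  \Sigma' = \Sigma - \frac{\Sigma_{\cdot e}\Sigma_{e\cdot}}{\Sigma_{ee}},$$

which is algebraically identical to junction-tree belief propagation for
pure Gaussian networks and to block conditioning of the joint — the test
suite verifies all three agree to $10^{-8}$ on hundreds of random
networks. At the sizes this package targets (tens to ~100 nodes) dense
linear algebra is effectively instantaneous, so no message-passing
schedule is needed. Nodes not d-connected to any evidence node
(`d_connected_nodes()`, Bayes-ball rules with colliders activated by
evidence descendants) keep their prior parameters *bit-exactly*: their
covariances with the evidence set are structural zeros, so the rank-one
updates cannot move them.

## From beliefs to flux constraints

For gene $g$ the predicted fold change is
$\mathrm{FC}_g = \hat\mu_g^{\text{post}} / \bar x_g$, posterior mean over
baseline sample mean. Because every fitted regression plane passes through
the sample means, evidence placed exactly at the evidence node's baseline
mean yields $\mathrm{FC} \equiv 1$ for every gene — a useful end-to-end
identity that the tests exercise.

Reactions catalyzed by several mapped enzymes receive the **arithmetic
mean** of their genes' fold changes. One post-translational rule is
supported: a modifier gene (a kinase such as PDK1 acting on pyruvate
dehydrogenase) with predicted fold change $\alpha$ multiplies its target
reaction's fold change by $1/\alpha$, encoding inhibitory phosphorylation
that mRNA of the target cannot reflect. Several rules composing on one
reaction multiply.

Each constrained reaction $j$ contributes a soft target row
$\Phi_j \approx \phi^{\text{base}}_j \cdot \mathrm{FC}_j$ with an error
variance $\varepsilon_j$. In the original application those variances come
from measured uptake/release rates; since such measurements are external
to this package, `build_target_vector()` defaults to a configurable
relative standard deviation (10% of $|\phi^{\text{base}}_j|$, with a
fallback scale for zero baselines) and accepts explicit per-row standard
deviations when measurement-derived values exist.

## The steady-state flux problem

With stoichiometric matrix $E$ (metabolites × reactions) and flux vector
$\Phi$, internal metabolites must balance, $E_{\text{int}}\Phi = 0$, while
external metabolites may exchange freely. Irreversibility and capacity
bounds form $G\Phi \ge h$. Reversible reactions are single signed columns
(never split). Two solvers operate on this polytope:

* `fba_optimize()` maximizes a linear objective $c^\top\Phi$ (net ATP
  production in the shipped fixtures). Degenerate optima are detected by
  re-optimizing a fixed generic direction on the optimal face and flagged
  with a warning.
* `lsei_solve()` minimizes the inverse-variance weighted residual
  $\sum_r (A_r\Phi - b_r)^2/\varepsilon_r$ subject to the equalities and
  inequalities. Equalities are eliminated by an orthonormal null-space
  basis; the reduced problem is an inequality-constrained QP. Weighting by
  $1/\varepsilon_r$ is the standard generalized-least-squares choice and
  reduces to unweighted least squares when all variances are equal.

Numerical choices: the LP backend is an exact two-phase revised simplex
with Bland's anticycling rule and fresh dense factorizations per iteration
— at tens of variables this costs nothing and avoids the tableau drift
and degeneracy pathologies of faster implementations. Leftover phase-1
artificials are pivoted out (or their redundant rows dropped) before
phase 2. Infeasibility is certified by a positive phase-1 optimum;
unboundedness by an entering column with no blocking ratio. In
`lsei_solve()`, when the reduced Hessian is singular the unconstrained
minimizer uses the pseudoinverse (minimum-norm solution); if inequalities
are active in that situation a ridge of $10^{-9}$ times the Hessian scale
selects among minimizers, a perturbation far below the $10^{-6}$
agreement the tests demand of well-posed problems.

## Sampling the feasible flux set

`reduce_polytope()` re-parameterizes the polytope on the affine subspace
$\Phi = \Phi_0 + Nz$ ($N$ orthonormal null-space basis of
$E_{\text{int}}$), rewrites the inequalities over $z$, computes the
Chebyshev center by LP, and measures per-dimension LP extents — which
double as a boundedness certificate: a uniform distribution over an
unbounded polytope is undefined, so unbounded directions are an error.

`mirror_sample()` runs a random-walk Metropolis chain whose Gaussian
proposals are **reflected specularly** off each inequality hyperplane they
cross, repeatedly until the candidate is interior (at most 1,000
reflections, after which the proposal is rejected with an actionable
warning). Reflection is an involution and preserves proposal symmetry, so:

* with **no soft target rows** every reflected proposal is accepted and
  the stationary distribution is exactly uniform on the polytope — the
  analytic fixtures (interval, simplex, cut cube) validate means and
  variances at 50,000 draws;
* with **soft target rows** the target is the Gaussian likelihood
  $\exp\{-\tfrac12\sum_r (A_r\Phi - b_r)^2/\varepsilon_r\}$ restricted to
  the polytope, and reflected proposals are accepted by the Metropolis
  ratio. This is the behavior required for the evidence sweep to be
  informative: the fold-change targets enter the flux problem only as
  soft rows, so a strictly uniform sampler would return identical
  summaries at every evidence value.

Jump scale: for uniform targets, 0.5 × the per-dimension LP width keeps
acceptance (and mixing) high on low-dimensional polytopes. For
likelihood-weighted targets that scale is far too coarse — the posterior
concentrates on a scale set by the target variances, not by the polytope —
so the proposal standard deviation is capped at
$2.4/\sqrt{d}\,\cdot\,\mathrm{sd}_{\text{post}}$ per dimension (the
classical random-walk scaling), with $\mathrm{sd}_{\text{post}}$ from the
diagonal of the inverse reduced Hessian when it is nonsingular. Chains
start at the least-squares fit (the mode of the likelihood target); a
start on the boundary is nudged toward the Chebyshev center by $10^{-6}$
of the polytope diameter. Chain $i$ is seeded `seed + i`, making every
sample set bit-reproducible under one master seed.

Defaults follow the protocol this package implements: 100,000 iterations,
2,000 burn-in, and four chains (so the multi-chain diagnostic is
defined).

### Convergence diagnostics

* `geweke_z()` compares the means of the first 10% and the last 50% of a
  chain, standardized by spectral (autoregressive, AIC-selected) estimates
  of each window's variance of the mean; under stationarity the score is
  asymptotically standard normal. Calibration on i.i.d. chains
  (rejection rate at $|z| > 1.96$ close to 5%) is part of the test suite.
* `gelman_rubin()` computes the potential scale reduction factor
  $\sqrt{((n-1)/n\,W + B/n)/W}$ from $\ge 2$ chains; values near 1
  indicate agreement, and the suite checks both a converged quartet
  (within $[0.99, 1.01]$ at $n = 10^4$) and a divergent pair ($> 3$).
  Default pass thresholds, where flags are reported: $|z| < 1.96$ and
  PSRF $< 1.1$, both configurable; constant flux coordinates are flagged
  rather than scored.

## Synthetic fixtures: what they emulate, and what they do not

`random_gbn_dataset()` draws a DAG with a uniform topological order and
independent Bernoulli edges, linear-Gaussian parameters in configurable
ranges, and ancestral samples at a microarray-like scale (root means near
9.5 log2 units, matching a basal transcription-factor level; evidence
sweeps typically span 8–13). It supports oracle testing (exact joint
moments known) and parameter-recovery studies.

`toy_brain_model()` is a fixed 7-reaction, 9-metabolite cartoon of brain
energy metabolism: capped glucose uptake, a two-step glycolysis-like
branch yielding 2 ATP and pyruvate, a reversible lactate exchange (brain
tissue both exports and consumes lactate), and a lumped
pyruvate-dehydrogenase/TCA/oxidative-phosphorylation reaction yielding
15 ATP per pyruvate under a capped oxygen supply, closed by an ATP drain.
All coefficients are integers; the polytope is bounded; the FBA optimum
(95 ATP-units at full oxygen, 20 anaerobically) is hand-checkable.

`regulated_toy_system()` wires a transcription factor onto enzyme
transcripts mapped to those reactions with all-positive slopes, plus a
kinase-like modifier gene (weaker slope, 0.2 vs. 0.6 on the directly
regulated dehydrogenase transcript) wired through the $1/\alpha$ rule —
so the ground truth is a monotone increasing objective response, which the
pipeline tests consume. A second condition reuses the structure with
slopes damped by 0.4, emulating a blunted regulatory program in disease;
comparative sweeps then show the control condition responding more
strongly than the disease condition, with no disease-specific logic
anywhere in the pipeline. The baseline flux vector is a hand-chosen
strictly interior feasible point standing in for a basal-condition fit.

None of the generators emulate probe-level effects, batch effects, heavy
tails or missingness of real microarray data, nor the scale (dozens of
metabolites, ~70 reactions) of a curated brain model. Passing tests
therefore demonstrate correctness of the machinery — exact inference,
constrained fitting, sampler distribution, diagnostic calibration — not
robustness to real-data artifacts.

## Problem sizes used by the checks

The test suite and the acceptance script regenerate everything from code:
200 random networks (≤15 nodes) for the inference oracle; 100 replicate
datasets of $n = 5{,}000$ samples from a fixed 15-node network for slope
recovery (for every slope, the 99% CI covers the truth in ≥95% of
replicates — the per-slope reading of CI calibration); 100 random
constrained least-squares problems against a brute-force active-set KKT
oracle; 50,000 post-burn-in draws per analytic polytope; and a full
2-condition × 6-evidence-value sweep (12 flux models) run at 5,000
iterations per chain, a size chosen so the whole suite completes in about
half a minute while leaving the protocol defaults (100,000/2,000) intact
in the configuration.

## Known limitations

* Regulation is one-way: the BN constrains metabolism; metabolic state
  does not feed back onto gene expression.
* Only hard (point) evidence is supported; soft evidence and
  discrete/hybrid nodes are out of scope.
* Boolean gene–protein–reaction logic (AND/OR) is not modeled; multiple
  enzymes average, and the single $1/\alpha$ modifier rule is the only
  post-translational mechanism.
* The proportionality assumption — reaction capacity scales with the
  mRNA fold change of its enzymes — is inherited from the modeling
  framework and is strongest for moderate perturbations.
* The mirror sampler is exact but not adaptive; very elongated polytopes
  may need a hand-tuned `jump_scale`.
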