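# bnflux

Integrating probabilistic gene-regulatory networks into constraint-based
models of metabolism.

## The problem

Transcriptional regulation shapes metabolic capacity, but the two are
usually modeled apart: regulatory pathways as graphical models over
expression data, metabolism as a stoichiometric polytope of steady-state
fluxes. `bnflux` is for systems biologists who want to ask *what happens
to the flux distribution when a transcription factor is pushed to a
hypothetical abundance* — for example, how activating a hypoxia-style
program shifts brain energy metabolism between aerobic respiration and
anaerobic glycolysis, and whether a diseased regulatory program responds
as strongly as a healthy one.

## The method

1. **Gaussian Bayesian network.** The pathway DAG is parameterized from
   expression data by per-node OLS regressions on parents, giving local
   models $X_i \mid \mathrm{pa}(X_i) \sim \mathcal N(\beta_{0i} + \sum_j
   \beta_{ij}X_j,\ \sigma_i^2)$ — jointly one multivariate normal.
2. **Exact evidence propagation.** Clamping a node to a value $v$ and
   conditioning the joint Gaussian yields the exact posterior mean and
   variance of every d-connected node.
3. **Fold-change constraints.** For each enzyme,
   $\mathrm{FC} = \mu_{\text{post}}/\bar x$; multiple enzymes on one
   reaction average; a kinase modifier with fold change $\alpha$
   multiplies its target reaction by $1/\alpha$. Each constrained reaction
   contributes a soft row $\Phi_j \approx \phi^{\text{base}}_j \cdot
   \mathrm{FC}_j$ with an error variance.
4. **Constrained flux fit.** `lsei_solve()` minimizes the
   inverse-variance weighted residual subject to $E_{\text{int}}\Phi = 0$
   and $G\Phi \ge h$ (least squares with equalities and inequalities);
   `fba_optimize()` gives the LP optimum of a linear objective such as net
   ATP production.
5. **Mirror MCMC.** The feasible polytope is sampled by a random-walk
   chain whose proposals reflect specularly off the inequality
   hyperplanes — exactly uniform when no target rows are present, and the
   target-likelihood posterior over the polytope when they are — with
   Geweke and Gelman–Rubin convergence diagnostics.
6. **Evidence sweep.** Per condition (e.g. control vs. disease expression
   sets), the whole chain — fit, propagate, constrain, solve, sample — is
   repeated over a grid of evidence values (default six values over
   8–13), yielding objective response curves and per-reaction flux
   fold-change reports.

## Worked example

The package ships generators for a fully synthetic but biologically shaped
system: a 7-reaction brain-energy-metabolism cartoon (capped glucose and
oxygen uptake, glycolysis-like branch, reversible lactate exchange, lumped
TCA/oxidative phosphorylation, ATP drain) and a transcription factor
regulating its enzymes, with a damped second condition emulating a blunted
disease program.

```r
library(bnflux)

rt  <- regulated_toy_system(seed = 11)
cfg <- chain_config(iterations = 4000, burn_in = 1000, chains = 2, seed = 5)
sp  <- sweep_spec("TF", evidence_values = c(8, 9.5, 11, 13),
                  baseline_flux = rt$baseline_flux, config = cfg)
res <- run_sweep(sp, rt$dag, rt$x, rt$condition, rt$model, rt$map,
                 rt$objective)
atp_curve(res)
```

```
  condition evidence_value     mean       se
1   control            8.0 49.77474 0.138289
2   control            9.5 53.12114 0.138289
3   control           11.0 56.33924 0.138289
4   control           13.0 60.44642 0.138289
5   disease            8.0 51.78294 0.138289
6   disease            9.5 53.11818 0.138289
7   disease           11.0 54.42080 0.138289
8   disease           13.0 56.10893 0.138289
```

The ATP-drain objective rises with the clamped TF level in both
conditions, but the control curve climbs from 49.8 to 60.4 flux units
(+21%) while the damped disease program only reaches 56.1 (+8%): the same
perturbation buys less metabolic response from the blunted network.
Per-reaction detail:

```r
head(flux_fold_change_report(res), 7)   # ratio of mean flux at TF=13 vs TF=8
```

```
  condition reaction  flux_low flux_high fold_change sign_change
1   control  R_GLCup  3.691180  4.695537    1.272096       FALSE
2   control     R_HK  3.691180  4.695537    1.272096       FALSE
3   control    R_PYK  3.691180  4.695537    1.272096       FALSE
4   control    R_LDH  4.556203  5.987384    1.314117       FALSE
5   control   R_O2up  8.478475 10.211070    1.204352       FALSE
6   control    R_PDH  2.826158  3.403690    1.204352       FALSE
7   control R_ATPase 49.774736 60.446423    1.214400       FALSE
```

Glycolytic throughput (`R_GLCup`–`R_PYK`) and the anaerobic lactate branch
(`R_LDH`) rise faster than the oxygen-limited aerobic branch (`R_PDH`) —
the lactate branch gains the most because the kinase modifier divides the
dehydrogenase reaction's fold change by the kinase's own induction
($1/\alpha$ rule).

A command-line front end with subcommands (`fit-bn`, `propagate`,
`constraints`, `fba`, `lsei`, `sample`, `sweep`, `fixtures`) is installed
at `system.file("cli", "bnflux.R", package = "bnflux")`.

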