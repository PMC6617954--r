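#' Specification of an evidence sweep
#'
#' Describes the full comparative experiment: per-condition expression
#' subsets, the perturbed transcription-factor node, the evidence grid, the
#' baseline flux vector to scale, and the MCMC configuration. The default
#' evidence grid is six equally spaced abundance values from 8 to 13; the
#' basal level (default 9.5) is used for labeling and reference only.
#'
#' @param evidence_node node id receiving evidence (e.g. the
#'   transcription-factor transcript)
#' @param evidence_values numeric vector of absorbed abundance values
#'   (default `seq(8, 13, length.out = 6)`)
#' @param baseline_flux named numeric vector of basal fluxes to be scaled by
#'   predicted fold-changes (typically a basal-condition least-squares fit)
#' @param config a [chain_config()]
#' @param basal_level reference basal abundance of the evidence node
#'   (default 9.5)
#' @param rel_sd relative standard deviation for target-row error variances
#'   (see [build_target_vector()])
#' @param antilog passed to [compute_fold_changes()]
#' @return a `sweep_spec` list
#' @export
sweep_spec <- function(evidence_node,
                       evidence_values = seq(8, 13, length.out = 6),
                       baseline_flux, config = chain_config(),
                       basal_level = 9.5, rel_sd = 0.1, antilog = FALSE) {
  stopifnot(length(evidence_values) >= 1, inherits(config, "chain_config"))
  structure(list(evidence_node = evidence_node,
                 evidence_values = as.numeric(evidence_values),
                 baseline_flux = baseline_flux, config = config,
                 basal_level = basal_level, rel_sd = rel_sd,
                 antilog = antilog),
            class = "sweep_spec")
}

#' Run the full evidence sweep over conditions
#'
#' For each condition, a Gaussian BN is fitted by local regressions on that
#' condition's samples. For each evidence value, the posterior transcript
#' means are propagated, gene fold-changes are computed against the
#' condition's baseline means, aggregated onto reactions (modifier rules
#' applied), embedded as soft flux targets, fitted by constrained least
#' squares, and the resulting polytope is sampled uniformly. One flux model
#' is fitted per (condition, evidence value) pair — e.g. two conditions and
#' six evidence values yield twelve fitted flux models.
#'
#' @param spec a [sweep_spec()]
#' @param dag the regulatory `bn_dag`
#' @param x expression matrix (samples x genes) spanning all conditions
#' @param condition character vector of condition labels, one per row of `x`
#' @param model a `stoich_model`
#' @param map a `gene_reaction_map`
#' @param objective named objective weights (e.g. net ATP production)
#' @return object of class `sweep_result`: list with `records` (one entry
#'   per condition x evidence value: condition, evidence value, fold-change
#'   table, reaction fold-changes, lsei fit, sample summary, objective mean
#'   and SE), `conditions`, `evidence_values`, `spec`, `n_models`
#' @export
run_sweep <- function(spec, dag, x, condition, model, map, objective) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(dag, "bn_dag"),
            inherits(model, "stoich_model"),
            inherits(map, "gene_reaction_map"))
  if (nrow(x) != length(condition))
    stop("'condition' must label every row of the expression matrix")
  conditions <- unique(condition)
  base_problem <- steady_state_system(model, objective = objective)
  obj_w <- base_problem$objective

  records <- list()
  for (cd in conditions) {
    xc <- x[condition == cd, , drop = FALSE]
    bn <- fit_local_gaussians(xc, dag)
    for (ev in spec$evidence_values) {
      rec <- tryCatch({
        evidence <- stats::setNames(ev, spec$evidence_node)
        fcs <- compute_fold_changes(bn, xc, evidence, antilog = spec$antilog)
        rfc <- aggregate_reaction_fold_changes(fcs, map)
        rfc <- apply_modifier_rules(rfc, fcs, map)
        targets <- build_target_vector(spec$baseline_flux, rfc,
                                       model$rxns$id, rel_sd = spec$rel_sd)
        problem <- set_flux_targets(base_problem, targets)
        fit <- lsei_solve(problem)
        rp <- reduce_polytope(problem, phi0 = fit)
        fs <- mirror_sample(rp, spec$config)
        summ <- summarize_samples(fs)
        obj_draws <- drop(fs$samples %*% obj_w)
        list(condition = cd, evidence_value = ev,
             fold_changes = fcs, reaction_fold_changes = rfc,
             lsei_fit = fit, summary = summ,
             objective_mean = mean(obj_draws),
             objective_se = mcmc_se(obj_draws, fs$chain),
             diagnostics = diagnose_samples(fs))
      }, error = function(e)
        stop("sweep failed at condition '", cd, "', evidence value ", ev,
             ": ", conditionMessage(e), call. = FALSE))
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(list(records = records, conditions = conditions,
                 evidence_values = spec$evidence_values, spec = spec,
                 n_models = length(records)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Evidence sweep:", length(x$conditions), "condition(s) x",
      length(x$evidence_values), "evidence value(s) =",
      x$n_models, "fitted flux models\n")
  invisible(x)
}

#' Objective response curve over the evidence grid
#'
#' Per condition, the mean and Monte-Carlo standard error of the linear
#' objective (net ATP production in the brain application) at each absorbed
#' evidence value.
#'
#' @param result a `sweep_result`
#' @return data frame with columns `condition`, `evidence_value`, `mean`,
#'   `se`
#' @export
atp_curve <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  do.call(rbind, lapply(result$records, function(r)
    data.frame(condition = r$condition, evidence_value = r$evidence_value,
               mean = r$objective_mean, se = r$objective_se,
               stringsAsFactors = FALSE)))
}

#' Per-reaction flux fold-change between two evidence values
#'
#' Compares mean sampled fluxes at a low and a high evidence value within
#' each condition; the ratio high/low is reported per reaction. Reactions
#' whose mean flux changes sign (or sits at zero) between the two grid
#' points are flagged instead of ratioed, since a ratio across zero is not
#' interpretable.
#'
#' @param result a `sweep_result`
#' @param low,high evidence values present in the sweep grid (defaults: grid
#'   extremes)
#' @return data frame with columns `condition`, `reaction`, `flux_low`,
#'   `flux_high`, `fold_change` (NA when flagged), `sign_change`
#' @export
flux_fold_change_report <- function(result, low = NULL, high = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  if (is.null(low)) low <- min(result$evidence_values)
  if (is.null(high)) high <- max(result$evidence_values)
  find <- function(cd, ev) {
    for (r in result$records)
      if (r$condition == cd && isTRUE(all.equal(r$evidence_value, ev)))
        return(r)
    stop("no sweep record for condition '", cd, "' at evidence value ", ev)
  }
  out <- list()
  for (cd in result$conditions) {
    lo <- find(cd, low)$summary
    hi <- find(cd, high)$summary
    sgn <- sign(lo$mean) * sign(hi$mean)
    fc <- ifelse(sgn > 0, hi$mean / lo$mean, NA_real_)
    out[[cd]] <- data.frame(
      condition = cd, reaction = lo$reaction,
      flux_low = lo$mean, flux_high = hi$mean,
      fold_change = fc, sign_change = sgn <= 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
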