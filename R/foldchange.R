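#' Predicted gene fold-changes after evidence absorption
#'
#' For each requested gene, the fold change is the posterior mean after
#' evidence propagation divided by the gene's baseline sample mean in the
#' training expression data (numerator: belief-propagation estimate;
#' denominator: observed mean in the original data). Values are used on the
#' expression scale as stored; set `antilog = TRUE` to exponentiate
#' log2-scale means before forming the ratio.
#'
#' @param bn a `gbn` fitted on `x`
#' @param x the expression matrix the BN was fitted on (samples x genes)
#' @param evidence named numeric vector of evidence (node -> value)
#' @param genes character vector of genes to report; defaults to all
#'   non-evidence BN nodes
#' @param antilog if TRUE, fold changes are ratios of 2^mean values
#' @return data frame of class `fold_change_table` with columns `gene`,
#'   `baseline`, `perturbed`, `fold_change`, `is_evidence`
#' @export
compute_fold_changes <- function(bn, x, evidence, genes = NULL,
                                 antilog = FALSE) {
  stopifnot(inherits(bn, "gbn"))
  beliefs <- propagate_evidence(bn, evidence)
  if (is.null(genes)) genes <- setdiff(bn$dag$nodes, names(evidence))
  bad <- setdiff(genes, bn$dag$nodes)
  if (length(bad)) stop("gene(s) not in network: ", paste(bad, collapse = ", "))
  missing_col <- setdiff(genes, colnames(x))
  if (length(missing_col))
    stop("gene(s) absent from expression matrix: ",
         paste(missing_col, collapse = ", "))

  baseline <- colMeans(x[, genes, drop = FALSE])
  perturbed <- beliefs$mean[genes]
  if (antilog) {
    baseline <- 2^baseline
    perturbed <- 2^perturbed
  }
  if (any(baseline <= 0))
    stop("nonpositive baseline mean for gene(s): ",
         paste(genes[baseline <= 0], collapse = ", "))
  out <- data.frame(
    gene = genes,
    baseline = unname(baseline),
    perturbed = unname(perturbed),
    fold_change = unname(perturbed / baseline),
    is_evidence = genes %in% names(evidence),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Read a gene-to-reaction map (and optional modifier rules) from TSV
#'
#' The map file has columns (reaction id, comma-separated gene ids); the
#' optional rules file has columns (target reaction id, modifier gene id).
#'
#' @param path map TSV path
#' @param rules_path optional modifier-rule TSV path
#' @return list of class `gene_reaction_map`: `genes` (named list,
#'   reaction -> character vector) and `rules` (data frame with columns
#'   `reaction`, `modifier`)
#' @export
read_gene_reaction_map <- function(path, rules_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  genes <- lapply(tab[[2L]], function(s) trimws(strsplit(s, ",")[[1L]]))
  names(genes) <- tab[[1L]]
  rules <- data.frame(reaction = character(0), modifier = character(0))
  if (!is.null(rules_path)) {
    rt <- utils::read.delim(rules_path, header = TRUE, colClasses = "character")
    rules <- data.frame(reaction = rt[[1L]], modifier = rt[[2L]],
                        stringsAsFactors = FALSE)
  }
  gene_reaction_map(genes, rules)
}

#' Construct a gene-to-reaction map
#'
#' @param genes named list: reaction id -> nonempty character vector of genes
#' @param rules data frame with columns `reaction` (target reaction) and
#'   `modifier` (modifier gene); each rule multiplies the target reaction's
#'   fold change by 1/alpha where alpha is the modifier gene's fold change
#'   (post-translational inhibition, e.g. a kinase inactivating its target
#'   enzyme)
#' @return a `gene_reaction_map`
#' @export
gene_reaction_map <- function(genes, rules = NULL) {
  if (is.null(rules))
    rules <- data.frame(reaction = character(0), modifier = character(0))
  if (any(vapply(genes, length, integer(1L)) == 0L))
    stop("every mapped reaction needs at least one gene")
  structure(list(genes = genes, rules = rules), class = "gene_reaction_map")
}

#' Aggregate gene fold-changes to reactions
#'
#' Where several enzymes map to one reaction the arithmetic mean of their
#' fold changes constrains the flux; a single-gene reaction inherits its
#' gene's fold change.
#'
#' @param fcs a `fold_change_table` from [compute_fold_changes()]
#' @param map a `gene_reaction_map`
#' @return named numeric vector of per-reaction fold changes
#' @export
aggregate_reaction_fold_changes <- function(fcs, map) {
  stopifnot(inherits(map, "gene_reaction_map"))
  fc <- stats::setNames(fcs$fold_change, fcs$gene)
  vapply(map$genes, function(gs) {
    miss <- setdiff(gs, names(fc))
    if (length(miss))
      stop("mapped gene(s) missing from fold-change table: ",
           paste(miss, collapse = ", "))
    mean(fc[gs])
  }, numeric(1L))
}

#' Apply modifier rules to reaction fold-changes
#'
#' Each rule divides the target reaction's fold change by the modifier
#' gene's predicted fold change alpha (i.e. multiplies by alpha^-1),
#' encoding inhibition of the enzyme by the modifier's product. Several
#' rules targeting one reaction compose multiplicatively.
#'
#' @param reaction_fcs named numeric vector from
#'   [aggregate_reaction_fold_changes()]
#' @param fcs the gene-level `fold_change_table`
#' @param map a `gene_reaction_map` carrying the rules
#' @return adjusted named numeric vector of reaction fold changes
#' @export
apply_modifier_rules <- function(reaction_fcs, fcs, map) {
  stopifnot(inherits(map, "gene_reaction_map"))
  rules <- map$rules
  if (NROW(rules) == 0L) return(reaction_fcs)
  fc <- stats::setNames(fcs$fold_change, fcs$gene)
  for (i in seq_len(nrow(rules))) {
    rxn <- rules$reaction[i]; mod <- rules$modifier[i]
    if (!rxn %in% names(reaction_fcs))
      stop("modifier rule targets unmapped reaction: ", rxn)
    if (!mod %in% names(fc))
      stop("modifier gene missing from fold-change table: ", mod)
    alpha <- fc[[mod]]
    if (alpha <= 0) stop("modifier gene ", mod, " has nonpositive fold change")
    reaction_fcs[[rxn]] <- reaction_fcs[[rxn]] / alpha
  }
  reaction_fcs
}

#' Build soft flux-target rows from reaction fold-changes
#'
#' For every constrained reaction j an approximate equation
#' `flux_j ~ baseline_j * FC_j` is emitted: a selector row in `A`, the scaled
#' target in `b`, and a per-row error variance. Targets act as soft
#' (least-squares) constraints; their error variances set the inverse
#' weights in [lsei_solve()]. By default the per-row standard deviation is
#' `rel_sd * |baseline_j|` (falling back to `rel_sd * max|baseline|` when the
#' baseline flux is zero); explicit standard deviations may be supplied
#' instead, e.g. when derived from measured uptake/release rates.
#'
#' @param baseline named numeric vector of baseline fluxes (full flux vector
#'   or at least the constrained reactions)
#' @param reaction_fcs named numeric vector of reaction fold changes
#' @param reactions character vector of all model reaction ids (column order
#'   of `A`)
#' @param rel_sd relative standard deviation for default error variances
#'   (fraction of |baseline flux|, default 0.1)
#' @param sd optional named numeric vector of explicit per-row standard
#'   deviations, overriding `rel_sd`
#' @return list with `A` (rows x reactions selector matrix), `b` (targets) and
#'   `var` (per-row error variances)
#' @export
build_target_vector <- function(baseline, reaction_fcs, reactions,
                                rel_sd = 0.1, sd = NULL) {
  cons <- names(reaction_fcs)
  bad <- setdiff(cons, reactions)
  if (length(bad))
    stop("constrained reaction(s) absent from model: ",
         paste(bad, collapse = ", "))
  miss <- setdiff(cons, names(baseline))
  if (length(miss))
    stop("no baseline flux for constrained reaction(s): ",
         paste(miss, collapse = ", "))
  A <- matrix(0, length(cons), length(reactions),
              dimnames = list(cons, reactions))
  for (j in cons) A[j, j] <- 1
  b <- baseline[cons] * reaction_fcs[cons]
  if (is.null(sd)) {
    s <- rel_sd * abs(baseline[cons])
    fallback <- rel_sd * max(abs(baseline), 1e-6)
    s[s == 0] <- fallback
  } else {
    miss_sd <- setdiff(cons, names(sd))
    if (length(miss_sd))
      stop("no standard deviation for row(s): ", paste(miss_sd, collapse = ", "))
    s <- sd[cons]
  }
  if (any(s <= 0)) stop("target-row standard deviations must be positive")
  list(A = A, b = unname(b), var = unname(s^2))
}

#' Write a fold-change table to TSV
#' @param fcs a `fold_change_table` or named numeric vector of reaction FCs
#' @param path output path
#' @export
write_fold_changes <- function(fcs, path) {
  if (is.numeric(fcs))
    fcs <- data.frame(reaction = names(fcs), fold_change = unname(fcs))
  utils::write.table(fcs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
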