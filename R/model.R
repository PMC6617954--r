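#' Read a stoichiometric metabolic model
#'
#' Two sources are supported. A pair of tab-separated tables: a reaction
#' table with columns `reaction_id`, `equation` (e.g. `"A + 2 B -> C"`;
#' `<->` also accepted), `reversible` (0/1), `lb`, `ub`; and a metabolite
#' table with columns `metabolite_id`, `external` (0/1). Alternatively an
#' SBML Level 3 document, where `boundaryCondition="true"` marks external
#' metabolites. The stoichiometric matrix E (metabolites x reactions) is
#' assembled with reactions as signed net columns (no splitting of
#' reversible reactions).
#'
#' @param reactions path to the reaction TSV, or an SBML file if
#'   `metabolites` is NULL and the file is XML
#' @param metabolites path to the metabolite TSV (NULL for SBML input)
#' @return object of class `stoich_model`: `mets` (data frame id/external),
#'   `rxns` (data frame id/reversible/lb/ub/equation), `S` (dense matrix,
#'   metabolites x reactions)
#' @export
read_model <- function(reactions, metabolites = NULL) {
  if (is.null(metabolites)) return(read_model_sbml(reactions))
  rx <- utils::read.delim(reactions, header = TRUE, stringsAsFactors = FALSE)
  mt <- utils::read.delim(metabolites, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("reaction_id", "equation", "reversible", "lb", "ub")
  if (!all(needed %in% names(rx)))
    stop("reaction table must have columns: ", paste(needed, collapse = ", "))
  if (!all(c("metabolite_id", "external") %in% names(mt)))
    stop("metabolite table must have columns metabolite_id, external")
  stoich_model(
    metabolite_ids = mt$metabolite_id,
    external = as.logical(as.integer(mt$external)),
    reaction_ids = rx$reaction_id,
    equations = rx$equation,
    reversible = as.logical(as.integer(rx$reversible)),
    lb = as.numeric(rx$lb), ub = as.numeric(rx$ub)
  )
}

#' Construct a stoichiometric model from reaction equations
#'
#' @param metabolite_ids character vector of unique metabolite ids
#' @param external logical vector: TRUE for external (boundary) metabolites,
#'   exempt from steady-state balancing
#' @param reaction_ids character vector of unique reaction ids
#' @param equations character vector of reaction equations
#'   (`"A + 2 B -> C"`); an empty side is allowed (pure sink/source)
#' @param reversible logical vector
#' @param lb,ub numeric flux bounds; irreversible reactions must have lb >= 0
#' @return a `stoich_model`
#' @export
stoich_model <- function(metabolite_ids, external, reaction_ids, equations,
                         reversible, lb, ub) {
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  m <- length(metabolite_ids); n <- length(reaction_ids)
  S <- matrix(0, m, n, dimnames = list(metabolite_ids, reaction_ids))
  for (j in seq_len(n)) {
    st <- parse_reaction_equation(equations[j])
    unknown <- setdiff(names(st), metabolite_ids)
    if (length(unknown))
      stop("reaction ", reaction_ids[j], " cites undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    S[names(st), j] <- st
  }
  if (any(!reversible & lb < 0))
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(reaction_ids[!reversible & lb < 0], collapse = ", "))
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(reaction_ids[lb > ub], collapse = ", "))
  structure(list(
    mets = data.frame(id = metabolite_ids, external = external,
                      stringsAsFactors = FALSE),
    rxns = data.frame(id = reaction_ids, equation = equations,
                      reversible = reversible, lb = lb, ub = ub,
                      stringsAsFactors = FALSE),
    S = S), class = "stoich_model")
}

# "2 A + B -> C" / "A <-> B" / "ATP ->" ; returns named coefficients
# (negative substrates, positive products), summing duplicates.
parse_reaction_equation <- function(eq) {
  arrow <- regmatches(eq, regexpr("<?->", eq))
  if (length(arrow) == 0L) stop("malformed reaction equation (no arrow): ", eq)
  sides <- strsplit(eq, "<?->")[[1L]]
  lhs <- if (length(sides) >= 1L) sides[1L] else ""
  rhs <- if (length(sides) >= 2L) sides[2L] else ""
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    out <- numeric(0)
    for (t in terms) {
      if (t == "") stop("malformed reaction side: ", s)
      parts <- strsplit(t, "[[:space:]]+")[[1L]]
      if (length(parts) == 1L) {
        coefficient <- 1; met <- parts
      } else if (length(parts) == 2L &&
                 grepl("^[0-9.]+$", parts[1L])) {
        coefficient <- as.numeric(parts[1L]); met <- parts[2L]
      } else stop("malformed term '", t, "' in equation: ", eq)
      out[met] <- if (met %in% names(out)) out[[met]] + sign * coefficient
                  else sign * coefficient
    }
    out
  }
  l <- parse_side(lhs, -1)
  r <- parse_side(rhs, +1)
  st <- l
  for (m in names(r)) st[m] <- if (m %in% names(st)) st[[m]] + r[[m]] else r[[m]]
  st[st != 0]
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model:", nrow(x$mets), "metabolites (",
      sum(!x$mets$external), "internal ),", nrow(x$rxns), "reactions\n")
  invisible(x)
}

#' Write a stoichiometric model to reaction/metabolite TSV files
#' @param model a `stoich_model`
#' @param reactions,metabolites output paths
#' @export
write_model <- function(model, reactions, metabolites) {
  utils::write.table(
    model$rxns[, c("id", "equation", "reversible", "lb", "ub")],
    reactions, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("reaction_id", "equation", "reversible", "lb", "ub"))
  utils::write.table(
    data.frame(metabolite_id = model$mets$id,
               external = as.integer(model$mets$external)),
    metabolites, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reactions)
}

# --- SBML Level 3 (minimal core subset) ---------------------------------

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(sp, "id")
  external <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx)
  ids <- xml2::xml_attr(rx, "id")
  rev_ <- tolower(xml2::xml_attr(rx, "reversible")) %in% "true"
  lb <- as.numeric(xml2::xml_attr(rx, "lowerFluxBound"))
  ub <- as.numeric(xml2::xml_attr(rx, "upperFluxBound"))
  lb[is.na(lb)] <- ifelse(rev_[is.na(lb)], -Inf, 0)
  ub[is.na(ub)] <- Inf
  eqs <- character(n)
  for (j in seq_len(n)) {
    side <- function(tag) {
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0L) return("")
      s <- xml2::xml_attr(refs, "species")
      k <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      k[is.na(k)] <- 1
      paste(ifelse(k == 1, s, paste(format_coef(k), s)), collapse = " + ")
    }
    eqs[j] <- paste(side("listOfReactants"),
                    if (rev_[j]) "<->" else "->", side("listOfProducts"))
  }
  stoich_model(met_ids, external, ids, trimws(eqs), rev_, lb, ub)
}

format_coef <- function(k) {
  ifelse(k == round(k), format(as.integer(round(k))), format(k, digits = 15))
}

#' Write a stoichiometric model as SBML Level 3
#'
#' Minimal core document: species carry `boundaryCondition` for external
#' metabolites; reactions carry `reversible` and custom `lowerFluxBound` /
#' `upperFluxBound` attributes mirroring the tabular format.
#'
#' @param model a `stoich_model`
#' @param path output path
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "model")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    xml2::xml_add_child(los, "species",
      id = model$mets$id[i], compartment = "c",
      boundaryCondition = tolower(as.character(model$mets$external[i])),
      hasOnlySubstanceUnits = "false", constant = "false")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$rxns))) {
    rxn <- xml2::xml_add_child(lor, "reaction",
      id = model$rxns$id[j],
      reversible = tolower(as.character(model$rxns$reversible[j])),
      lowerFluxBound = format(model$rxns$lb[j], digits = 15),
      upperFluxBound = format(model$rxns$ub[j], digits = 15))
    col <- model$S[, j]
    subs <- names(col)[col < 0]; prods <- names(col)[col > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rxn, "listOfReactants")
      for (m in subs)
        xml2::xml_add_child(lr, "speciesReference", species = m,
          stoichiometry = format(-col[[m]], digits = 15), constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rxn, "listOfProducts")
      for (m in prods)
        xml2::xml_add_child(lp, "speciesReference", species = m,
          stoichiometry = format(col[[m]], digits = 15), constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# --- steady-state constraint system -------------------------------------

#' Assemble the steady-state flux problem for a model
#'
#' Internal metabolites must balance at steady state (`E_int Phi = 0`);
#' external metabolites may have nonzero net flux and contribute no
#' equality row. Inequalities `G Phi >= h` encode irreversibility
#' (`Phi_j >= 0`) and any finite bounds. The linear objective `c` defaults
#' to zero and is typically set to net ATP production.
#'
#' @param model a `stoich_model`
#' @param objective optional named numeric vector of objective weights
#'   (reaction id -> weight)
#' @return object of class `flux_problem`: `E` (equality matrix over internal
#'   metabolites), `f` (zero rhs), `G`, `h` (inequalities, `G Phi >= h`),
#'   `objective`, `A`, `b`, `var` (soft target rows, empty until set),
#'   `reactions` (column ids)
#' @export
steady_state_system <- function(model, objective = NULL) {
  stopifnot(inherits(model, "stoich_model"))
  internal <- !model$mets$external
  E <- model$S[internal, , drop = FALSE]
  n <- nrow(model$rxns)
  rid <- model$rxns$id
  G <- matrix(0, 0, n, dimnames = list(NULL, rid))
  h <- numeric(0)
  for (j in seq_len(n)) {
    lbj <- model$rxns$lb[j]; ubj <- model$rxns$ub[j]
    if (!model$rxns$reversible[j]) lbj <- max(lbj, 0)
    if (is.finite(lbj)) {
      row <- numeric(n); row[j] <- 1
      G <- rbind(G, row); h <- c(h, lbj)
      rownames(G)[nrow(G)] <- paste0(rid[j], "_lb")
    }
    if (is.finite(ubj)) {
      row <- numeric(n); row[j] <- -1
      G <- rbind(G, row); h <- c(h, -ubj)
      rownames(G)[nrow(G)] <- paste0(rid[j], "_ub")
    }
  }
  cvec <- stats::setNames(numeric(n), rid)
  if (!is.null(objective)) {
    bad <- setdiff(names(objective), rid)
    if (length(bad)) stop("objective cites unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    cvec[names(objective)] <- objective
  }
  structure(list(
    E = E, f = numeric(nrow(E)), G = G, h = h, objective = cvec,
    A = matrix(0, 0, n, dimnames = list(NULL, rid)),
    b = numeric(0), var = numeric(0), reactions = rid
  ), class = "flux_problem")
}

#' Attach soft target rows to a flux problem
#'
#' @param problem a `flux_problem`
#' @param targets list with `A`, `b`, `var` from [build_target_vector()]
#' @return the problem with approximate rows set
#' @export
set_flux_targets <- function(problem, targets) {
  stopifnot(inherits(problem, "flux_problem"))
  if (ncol(targets$A) != length(problem$reactions))
    stop("target rows have wrong width")
  problem$A <- targets$A
  problem$b <- targets$b
  problem$var <- targets$var
  problem
}

#' @export
print.flux_problem <- function(x, ...) {
  cat("Flux problem:", length(x$reactions), "fluxes,",
      nrow(x$E), "equalities,", nrow(x$G), "inequalities,",
      nrow(x$A), "soft target row(s)\n")
  invisible(x)
}
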