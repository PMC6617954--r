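#' Validate a directed acyclic regulatory graph
#'
#' Builds a `bn_dag` object from an edge list, checking for self-loops,
#' duplicate edges and cycles, and caching a topological order of the nodes.
#' Regulatory networks represented as Bayesian networks must be acyclic:
#' feedback loops are rejected with a report of one offending cycle.
#'
#' @param edges two-column matrix or data frame of (parent, child) pairs,
#'   or a list of length-2 character vectors. May be empty if `nodes` is given.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   union of edge endpoints. Must contain every edge endpoint.
#' @return an object of class `bn_dag` with components `nodes`, `edges`
#'   (two-column character matrix), `parents` (named list of parent sets) and
#'   `order` (a topological order, parents before children).
#' @examples
#' dag <- validate_dag(rbind(c("A", "B"), c("B", "C")))
#' dag$order
#' @export
validate_dag <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges) && !is.matrix(edges)) edges <- do.call(rbind, edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("'edges' must be a two-column (parent, child) structure")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")

  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  nodes <- as.character(nodes)
  if (length(nodes) == 0L)
    stop("empty graph: supply a nonempty edge list or an explicit node list")
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  missing <- setdiff(as.vector(edges), nodes)
  if (length(missing))
    stop("edge endpoint(s) not in node list: ", paste(missing, collapse = ", "))
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops))
    stop("self-loop on node(s): ", paste(unique(edges[loops, 1L]), collapse = ", "))
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE]
    stop("duplicate edge(s): ",
         paste(unique(paste(d[, 1L], d[, 2L], sep = " -> ")), collapse = ", "))
  }

  parents <- lapply(stats::setNames(nodes, nodes), function(v)
    unname(edges[edges[, 2L] == v, 1L]))

  ord <- topological_order(nodes, parents)

  structure(
    list(nodes = nodes, edges = edges, parents = parents, order = ord),
    class = "bn_dag"
  )
}

# Kahn's algorithm; on a cycle, reports one cycle found by parent-walking
# within the unorderable remainder.
topological_order <- function(nodes, parents) {
  indeg <- vapply(parents, length, integer(1L))[nodes]
  children <- lapply(stats::setNames(nodes, nodes), function(v) character(0))
  for (v in nodes) for (p in parents[[v]])
    children[[p]] <- c(children[[p]], v)
  queue <- nodes[indeg == 0L]
  ord <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in children[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < length(nodes)) {
    rest <- setdiff(nodes, ord)
    # walk parents (restricted to the remainder) until a node repeats
    path <- rest[1L]
    repeat {
      nxt <- intersect(parents[[path[1L]]], rest)[1L]
      if (nxt %in% path) {
        cyc <- c(nxt, rev(path[seq_len(match(nxt, path))]))
        stop("cycle detected: ", paste(cyc, collapse = " -> "))
      }
      path <- c(nxt, path)
    }
  }
  ord
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Directed acyclic graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Nodes d-connected to a set of evidence nodes
#'
#' Standard d-separation on the DAG: paths are traced with the Bayes-ball
#' rules, so a collider transmits dependence only when it (or one of its
#' descendants) carries evidence, while chains and forks are blocked at
#' evidence nodes. Nodes d-connected to at least one evidence node are
#' exactly those whose posterior can change when that evidence is absorbed.
#'
#' @param dag a `bn_dag`
#' @param evidence_nodes character vector of node ids carrying evidence
#' @return character vector of non-evidence nodes d-connected to the evidence
#' @examples
#' dag <- validate_dag(rbind(c("A", "C"), c("B", "C")))
#' d_connected_nodes(dag, "A")  # collider blocked: only "C"
#' d_connected_nodes(dag, "C")  # collider activated: "A" and "B"
#' @export
d_connected_nodes <- function(dag, evidence_nodes) {
  stopifnot(inherits(dag, "bn_dag"))
  evidence_nodes <- as.character(evidence_nodes)
  if (!all(evidence_nodes %in% dag$nodes))
    stop("evidence node(s) not in graph: ",
         paste(setdiff(evidence_nodes, dag$nodes), collapse = ", "))

  nodes <- dag$nodes
  parents <- dag$parents
  children <- lapply(stats::setNames(nodes, nodes), function(v) character(0))
  for (v in nodes) for (p in parents[[v]])
    children[[p]] <- c(children[[p]], v)

  # The posterior of T can move when evidence enters at e iff T is
  # d-connected to e given the remaining evidence; union over e.
  reach <- character(0)
  for (e in evidence_nodes) {
    reach <- union(reach,
                   bayes_ball(e, setdiff(evidence_nodes, e),
                              nodes, parents, children))
  }
  sort(setdiff(reach, evidence_nodes))
}

# Single-source Bayes ball: nodes d-connected to `source` given `cond`.
# State is (node, direction): "up" = entered from a child, "down" = from a
# parent. Colliders pass only when the node or a descendant is in `cond`.
bayes_ball <- function(source, cond, nodes, parents, children) {
  anc <- character(0)
  frontier <- cond
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), anc)
  }
  is_cond <- stats::setNames(nodes %in% cond, nodes)
  in_anc <- stats::setNames(nodes %in% anc, nodes)

  seen <- character(0)
  reach <- character(0)
  queue <- list(list(node = source, dir = "up"))
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    key <- paste(st$node, st$dir)
    if (key %in% seen) next
    seen <- c(seen, key)
    v <- st$node
    if (!is_cond[[v]] && v != source) reach <- union(reach, v)
    if (st$dir == "up") {
      if (!is_cond[[v]]) {
        for (p in parents[[v]]) queue <- c(queue, list(list(node = p, dir = "up")))
        for (w in children[[v]]) queue <- c(queue, list(list(node = w, dir = "down")))
      }
    } else {
      if (!is_cond[[v]]) {
        for (w in children[[v]]) queue <- c(queue, list(list(node = w, dir = "down")))
      }
      if (is_cond[[v]] || in_anc[[v]]) {
        for (p in parents[[v]]) queue <- c(queue, list(list(node = p, dir = "up")))
      }
    }
  }
  reach
}

#' Read a DAG edge list from TSV
#'
#' Expects a headered two-column tab-separated file (parent, child).
#'
#' @param path file path
#' @param nodes optional explicit node list passed to [validate_dag()]
#' @return a `bn_dag`
#' @export
read_dag <- function(path, nodes = NULL) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 2L) stop("DAG TSV must have two columns (parent, child)")
  validate_dag(as.matrix(tab[, 1:2]), nodes = nodes)
}
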