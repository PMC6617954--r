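#' Read an expression matrix and condition labels from TSV
#'
#' The expression file has a first column of sample identifiers and one
#' column per gene (values on the scale provided, e.g. log2 microarray
#' intensity). The optional label file is a two-column TSV (sample id,
#' condition).
#'
#' @param path expression TSV path
#' @param labels_path optional condition-label TSV path
#' @return a list with `x` (numeric samples-by-genes matrix, sample ids as
#'   row names) and `condition` (character vector aligned to rows, or NULL)
#' @export
read_expression <- function(path, labels_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs a sample column plus genes")
  x <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(tab[[1L]])
  cond <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, header = TRUE,
                             colClasses = "character")
    cond <- stats::setNames(lab[[2L]], lab[[1L]])[rownames(x)]
    if (anyNA(cond)) stop("condition label missing for some samples")
    cond <- unname(cond)
  }
  list(x = x, condition = cond)
}

check_expression <- function(x, dag) {
  if (anyNA(x)) stop("expression matrix contains missing values")
  absent <- setdiff(dag$nodes, colnames(x))
  if (length(absent))
    stop("network node(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  invisible(x)
}

#' Fit local Gaussian models of a Bayesian network by regression
#'
#' Each node is regressed (ordinary least squares) on its parents in the
#' DAG; the intercept, one slope per parent and the residual variance
#' (unbiased, denominator n - p - 1) define the node's local conditional
#' Gaussian. Parentless nodes get their sample mean and unbiased sample
#' variance. Together with the DAG the local models define the joint
#' density as a product of conditionals.
#'
#' @param x numeric samples-by-genes matrix (no missing values; every node of
#'   `dag` must be a column)
#' @param dag a [validate_dag()] object
#' @return an object of class `gbn`: list with `dag` and `local`, the latter a
#'   named list with per-node `intercept`, `coef` (named by parent) and
#'   `resid_var`
#' @export
fit_local_gaussians <- function(x, dag) {
  stopifnot(inherits(dag, "bn_dag"))
  check_expression(x, dag)
  n <- nrow(x)
  local <- vector("list", length(dag$nodes))
  names(local) <- dag$nodes
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    p <- length(pa)
    if (n < p + 2L)
      stop("node ", v, ": ", n, " samples cannot support ", p,
           " parents (need at least parents + 2)")
    y <- x[, v]
    if (stats::var(y) == 0)
      stop("node ", v, " is constant-valued; cannot fit a local Gaussian")
    if (p == 0L) {
      local[[v]] <- list(intercept = mean(y), coef = stats::setNames(numeric(0), character(0)),
                         resid_var = stats::var(y))
    } else {
      X <- cbind(1, x[, pa, drop = FALSE])
      qr_ <- qr(X)
      if (qr_$rank < ncol(X))
        stop("node ", v, ": parent design is rank-deficient (collinear parents ",
             paste(pa, collapse = ", "), ")")
      beta <- qr.coef(qr_, y)
      res <- y - X %*% beta
      local[[v]] <- list(
        intercept = unname(beta[1L]),
        coef = stats::setNames(unname(beta[-1L]), pa),
        resid_var = sum(res^2) / (n - p - 1L)
      )
    }
  }
  structure(list(dag = dag, local = local), class = "gbn")
}

#' Construct a Gaussian BN from explicit local parameters
#'
#' Convenience constructor used by fixtures and tests: supply per-node
#' intercepts, parent slopes and residual variances directly.
#'
#' @param dag a `bn_dag`
#' @param intercept named numeric vector (one per node)
#' @param coef named list of named numeric vectors (slopes by parent); nodes
#'   may be omitted if parentless
#' @param resid_var named numeric vector of residual variances (>= 0)
#' @return a `gbn`
#' @export
gbn <- function(dag, intercept, coef = list(), resid_var) {
  stopifnot(inherits(dag, "bn_dag"))
  local <- vector("list", length(dag$nodes))
  names(local) <- dag$nodes
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    cf <- coef[[v]]
    if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
    if (!setequal(names(cf), pa))
      stop("node ", v, ": coefficient names must match its parent set")
    rv <- resid_var[[v]]
    if (is.null(rv) || rv < 0) stop("node ", v, ": residual variance must be >= 0")
    local[[v]] <- list(intercept = unname(intercept[[v]]),
                       coef = cf[pa], resid_var = unname(rv))
  }
  structure(list(dag = dag, local = local), class = "gbn")
}

#' @export
print.gbn <- function(x, ...) {
  cat("Gaussian Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges\n")
  invisible(x)
}

#' Joint multivariate Gaussian implied by a Gaussian BN
#'
#' A linear Gaussian BN is equivalent to a single multivariate normal.
#' Writing the structural equations X = b0 + B X + e with B the matrix of
#' parent slopes (strictly lower triangular in topological order) and e
#' independent noise with diagonal covariance D, the mean solves
#' mu = (I - B)^{-1} b0 and the covariance is (I - B)^{-1} D (I - B)^{-T}.
#'
#' @param bn a `gbn`
#' @return list with `mean` (named vector) and `cov` (matrix), ordered as
#'   `bn$dag$nodes`
#' @export
to_joint_gaussian <- function(bn) {
  stopifnot(inherits(bn, "gbn"))
  nodes <- bn$dag$nodes
  k <- length(nodes)
  B <- matrix(0, k, k, dimnames = list(nodes, nodes))
  b0 <- numeric(k); names(b0) <- nodes
  D <- numeric(k); names(D) <- nodes
  for (v in nodes) {
    lm_ <- bn$local[[v]]
    b0[v] <- lm_$intercept
    D[v] <- lm_$resid_var
    if (length(lm_$coef)) B[v, names(lm_$coef)] <- lm_$coef
  }
  IB <- diag(k) - B
  Ainv <- solve(IB)                       # (I - B)^{-1}, exists: DAG => nilpotent B
  mu <- drop(Ainv %*% b0)
  Sigma <- Ainv %*% diag(D, k) %*% t(Ainv)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(nodes, nodes)
  names(mu) <- nodes
  list(mean = mu, cov = Sigma)
}

#' Ancestral sampling from a Gaussian BN
#'
#' Draws each node in topological order from its local conditional given the
#' already-sampled parents.
#'
#' @param bn a `gbn`
#' @param n number of draws
#' @return numeric n-by-nodes matrix with gene columns
#' @export
sample_gbn <- function(bn, n) {
  stopifnot(inherits(bn, "gbn"), n >= 1)
  nodes <- bn$dag$nodes
  out <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in bn$dag$order) {
    lm_ <- bn$local[[v]]
    mu <- rep(lm_$intercept, n)
    for (p in names(lm_$coef)) mu <- mu + lm_$coef[[p]] * out[, p]
    out[, v] <- mu + stats::rnorm(n, 0, sqrt(lm_$resid_var))
  }
  out
}

#' Serialize a fitted Gaussian BN to JSON
#'
#' @param bn a `gbn`
#' @param path output path
#' @export
write_gbn <- function(bn, path) {
  stopifnot(inherits(bn, "gbn"))
  doc <- list(
    nodes = bn$dag$nodes,
    edges = apply(bn$dag$edges, 1L, function(r) list(parent = r[[1L]], child = r[[2L]])),
    local = lapply(bn$local, function(l)
      list(intercept = l$intercept, coef = as.list(l$coef), resid_var = l$resid_var))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Gaussian BN serialized by [write_gbn()]
#'
#' @param path JSON path
#' @return a `gbn`
#' @export
read_gbn <- function(path) {
  doc <- jsonlite::read_json(path)
  edges <- do.call(rbind, lapply(doc$edges, function(e) c(e$parent, e$child)))
  dag <- validate_dag(edges, nodes = unlist(doc$nodes))
  intercept <- lapply(doc$local, `[[`, "intercept")
  resid_var <- lapply(doc$local, `[[`, "resid_var")
  coef <- lapply(doc$local, function(l) unlist(l$coef))
  gbn(dag, intercept = intercept, coef = coef, resid_var = resid_var)
}
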