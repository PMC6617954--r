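# Spectral density of a chain at frequency zero, estimated by fitting an
# autoregressive model (Yule-Walker/AIC): s(0) = sigma2 / (1 - sum(ar))^2.
# This is the classic estimator used for the variance of an MCMC mean.
spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(length(x) - 1L,
                                            floor(10 * log10(length(x))))),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke stationarity z-score for one chain
#'
#' Tests equality of the chain mean over an early and a late window (by
#' default the first 10% and the last 50% of the chain). The difference of
#' window means is standardized by spectral estimates of each window's
#' variance of the mean, so that under stationarity the score is
#' asymptotically standard normal; large |z| indicates the chain has not
#' reached its stationary distribution.
#'
#' @param x numeric chain (one flux coordinate)
#' @param frac_first,frac_last window fractions (defaults 0.1 and 0.5)
#' @return the z-score, or NA (with a "constant window" attribute) when a
#'   window has zero variance
#' @export
geweke_z <- function(x, frac_first = 0.1, frac_last = 0.5) {
  n <- length(x)
  if (n < 100L) stop("chain too short for the Geweke diagnostic (need >= 100)")
  stopifnot(frac_first > 0, frac_last > 0, frac_first + frac_last <= 1)
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(n - n2 + 1L, n)]
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    out <- NA_real_
    attr(out, "constant") <- TRUE
    return(out)
  }
  s1 <- spectrum0(x1)
  s2 <- spectrum0(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares the pooled variance of several chains with the within-chain
#' variances:
#' `sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean within-chain
#' variance and `B = n * var(chain means)` the between-chain variance. The
#' statistic approaches 1 as the chains converge to a common stationary
#' distribution; values well above 1 indicate disagreement between chains.
#'
#' @param chains list of >= 2 numeric vectors of equal length (>= 10)
#' @return the potential scale reduction factor
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("the Gelman-Rubin diagnostic needs at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("chains too short (need length >= 10)")
  W <- mean(vapply(chains, stats::var, numeric(1L)))
  if (W == 0) stop("zero within-chain variance; statistic undefined")
  mu <- vapply(chains, mean, numeric(1L))
  B <- n * stats::var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report for a flux sample set
#'
#' Applies the Geweke test per chain (then reports the worst |z|) and the
#' Gelman-Rubin statistic across chains, per flux coordinate. Coordinates
#' that are constant across all draws are flagged rather than scored.
#'
#' @param fs a `flux_samples` (with >= 2 chains for the Gelman-Rubin column)
#' @param z_threshold pass threshold on |z| (default 1.96)
#' @param psrf_threshold pass threshold on the scale reduction factor
#'   (default 1.1)
#' @return data frame of class `mcmc_diagnostics` with columns `reaction`,
#'   `geweke_z` (worst over chains), `psrf`, `constant`, `pass`
#' @export
diagnose_samples <- function(fs, z_threshold = 1.96, psrf_threshold = 1.1) {
  stopifnot(inherits(fs, "flux_samples"))
  ids <- fs$reactions
  nch <- length(unique(fs$chain))
  res <- lapply(ids, function(r) {
    x <- fs$samples[, r]
    if (stats::var(x) == 0)
      return(data.frame(reaction = r, geweke_z = NA_real_, psrf = NA_real_,
                        constant = TRUE, pass = NA))
    zs <- vapply(unique(fs$chain), function(ch)
      geweke_z(x[fs$chain == ch]), numeric(1L))
    z <- zs[which.max(abs(zs))]
    psrf <- if (nch >= 2L)
      gelman_rubin(split(x, fs$chain)) else NA_real_
    data.frame(reaction = r, geweke_z = z, psrf = psrf, constant = FALSE,
               pass = abs(z) < z_threshold &&
                 (is.na(psrf) || psrf < psrf_threshold))
  })
  out <- do.call(rbind, res)
  class(out) <- c("mcmc_diagnostics", "data.frame")
  out
}
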