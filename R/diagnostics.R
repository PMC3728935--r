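#' Gelman-Rubin potential scale reduction factor
#'
#' Multi-chain convergence diagnostic: with \eqn{m} chains of length
#' \eqn{n}, between-chain variance \eqn{B} and mean within-chain variance
#' \eqn{W}, the statistic is
#' \deqn{\hat R = \sqrt{ \frac{(n-1)/n \; W + B/n}{W} }.}
#' Values near 1 indicate the chains have mixed; the conventional
#' acceptance bound is that the 97.5\% quantile across monitored parameters
#' stays below 1.2.
#'
#' @param chains A \code{posterior_chains} object, or a list of equal-length
#'   numeric vectors (one per chain) when \code{parameter} is \code{NULL}.
#' @param parameter Optional parameter name; default computes the statistic
#'   for every parameter.
#' @return Named numeric vector of \eqn{\hat R} values.
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  mats <- if (inherits(chains, "posterior_chains")) chains$chains
          else if (is.list(chains)) lapply(chains, as.matrix)
          else stop("'chains' must be posterior_chains or a list of chains")
  if (length(mats) < 2L) stop("need at least two chains")
  lens <- vapply(mats, nrow, 0L)
  if (length(unique(lens)) != 1L) stop("chains must have equal length")
  pars <- colnames(mats[[1]])
  if (is.null(pars)) pars <- paste0("par", seq_len(ncol(mats[[1]])))
  if (!is.null(parameter)) {
    if (!parameter %in% pars) stop("unknown parameter: ", parameter)
    sel <- parameter
  } else sel <- pars
  n <- lens[1]
  out <- vapply(sel, function(p) {
    j <- match(p, pars)
    x <- vapply(mats, function(m) m[, j], numeric(n))  # n x m
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
  names(out) <- sel
  out
}

#' Lag-k autocorrelation of a chain
#'
#' Sample correlation between the chain and its lag-\code{lag} shift. A
#' constant chain has no defined autocorrelation and raises an error rather
#' than returning 0.
#'
#' @param chain Numeric vector of draws.
#' @param lag Positive lag, smaller than \code{length(chain)}.
#' @export
autocorr <- function(chain, lag = 1L) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (lag < 1L || lag >= n) stop("'lag' must be in [1, length(chain) - 1]")
  head <- chain[seq_len(n - lag)]
  tail <- chain[seq_len(n - lag) + lag]
  if (stats::sd(head) == 0 || stats::sd(tail) == 0)
    stop("autocorrelation undefined for a constant chain")
  stats::cor(head, tail)
}

#' Convergence report for a multi-chain fit
#'
#' Computes per-parameter Gelman-Rubin statistics and, per parameter and
#' chain, the lag-1 autocorrelation of the retained (thinned) draws, then
#' summarises them the way the mixing criteria are usually stated: the
#' 97.5\% quantile of \eqn{\hat R} across parameters (accept < 1.2) and the
#' maximum absolute autocorrelation (accept <= 0.1). Constant chains
#' (possible for a parameter pinned by degenerate data) are skipped in the
#' autocorrelation scan.
#'
#' @param chains A \code{posterior_chains} object.
#' @param lag Lag for the autocorrelation scan.
#' @return List with \code{psrf} (named vector), \code{psrf_q975},
#'   \code{acf} (parameter x chain matrix), \code{max_abs_acf}.
#' @export
mcmc_diagnostics <- function(chains, lag = 1L) {
  stopifnot(inherits(chains, "posterior_chains"))
  psrf <- gelman_rubin(chains)
  acfs <- sapply(seq_along(chains$chains), function(ch) {
    m <- chains$chains[[ch]]
    vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      if (stats::sd(x) == 0) return(NA_real_)
      autocorr(x, lag)
    }, 0)
  })
  acfs <- matrix(acfs, nrow = length(chains$par_names),
                 dimnames = list(chains$par_names,
                                 paste0("chain", seq_along(chains$chains))))
  list(psrf = psrf,
       psrf_q975 = unname(stats::quantile(psrf, 0.975, type = 7)),
       acf = acfs,
       max_abs_acf = max(abs(acfs), na.rm = TRUE))
}
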