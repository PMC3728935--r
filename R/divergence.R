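#' Phenotypic divergence index from variance components
#'
#' The Q_ST proxy for phenotypic data:
#' \deqn{P_{ST} = \frac{c\,\sigma^2_B}{c\,\sigma^2_B + 2 h^2 \sigma^2_W}}
#' where \eqn{\sigma^2_B} is the between-population variance,
#' \eqn{\sigma^2_W} the within-population phenotypic variance, \eqn{c} the
#' proportion of the between-population variance assumed additive and
#' \eqn{h^2} the narrow-sense heritability. With \eqn{c = 1} and known
#' additive variances this equals Q_ST.
#'
#' Vectorised over all arguments; monotone increasing in \code{sigma2_B}
#' and \code{c}, decreasing in \code{sigma2_W} and \code{h2}.
#'
#' @param sigma2_B Between-population variance (>= 0).
#' @param sigma2_W Within-population phenotypic variance (>= 0; not both
#'   zero).
#' @param c Additive proportion of between-population variance, in (0, 1].
#' @param h2 Narrow-sense heritability, in (0, 1].
#' @return Value(s) in [0, 1].
#' @examples
#' pst_from_components(2, 1, c = 1, h2 = 1)   # 0.5
#' pst_from_components(2, 1, c = 1, h2 = 0.5) # 2/3
#' @export
pst_from_components <- function(sigma2_B, sigma2_W, c = 1, h2) {
  if (any(sigma2_B < 0) || any(sigma2_W < 0))
    stop("variance components must be non-negative")
  if (any(sigma2_B + sigma2_W == 0))
    stop("P_ST undefined when both variance components are zero")
  if (any(c <= 0) || any(c > 1)) stop("'c' must lie in (0, 1]")
  if (any(h2 <= 0) || any(h2 > 1)) stop("'h2' must lie in (0, 1]")
  num <- c * sigma2_B
  num / (num + 2 * h2 * sigma2_W)
}

#' Configuration for posterior P_ST computation
#'
#' @param c Additive proportion of between-population variance; the
#'   conventional assumption is \code{c = 1}.
#' @param h2 Heritability source: \code{NULL} to supply an
#'   \code{h2_posterior} at call time, or a fixed scalar in (0, 1].
#' @param fst_upper Upper 95\% quantile of neutral F_ST, the reference the
#'   posterior is compared against; in [0, 1).
#' @param within \code{"total"} uses \code{sigma2_family + sigma2_resid} as
#'   the within-population variance; \code{"residual-only"} uses
#'   \code{sigma2_resid} alone.
#' @export
pst_config <- function(c = 1, h2 = NULL, fst_upper = 0.05,
                       within = c("total", "residual-only")) {
  within <- match.arg(within)
  if (c <= 0 || c > 1) stop("'c' must lie in (0, 1]")
  if (!is.null(h2) && (h2 <= 0 || h2 > 1)) stop("'h2' must lie in (0, 1]")
  if (fst_upper < 0 || fst_upper >= 1) stop("'fst_upper' must lie in [0, 1)")
  structure(list(c = c, h2 = h2, fst_upper = fst_upper, within = within),
            class = "pst_config")
}

#' Posterior distribution of P_ST for one rearing environment
#'
#' Evaluates the divergence index per retained draw of the divergence model
#' (random population + family), pairing heritability draws by index — with
#' equal MCMC regimes this is a valid Monte-Carlo approximation of the two
#' independent posteriors.
#'
#' @param stream_chains A \code{posterior_chains} from the divergence model;
#'   must contain \code{sigma2_population}, \code{sigma2_family},
#'   \code{sigma2_resid}.
#' @param h2 An \code{h2_posterior} (same number of retained draws), a
#'   numeric vector of matching length, or a scalar; defaults to
#'   \code{config$h2}.
#' @param config A \code{\link{pst_config}}.
#' @param stream Label stored in the result.
#' @return Object of class \code{pst_posterior}: draws, median, 2.5/97.5\%
#'   quantiles and the selection verdict against \code{fst_upper}.
#' @export
pst_posterior <- function(stream_chains, h2 = NULL, config = pst_config(),
                          stream = "stream") {
  stopifnot(inherits(stream_chains, "posterior_chains"),
            inherits(config, "pst_config"))
  m <- as.matrix(stream_chains)
  if (!"sigma2_population" %in% colnames(m))
    stop("divergence model must include a random population term")
  if (is.null(h2)) h2 <- config$h2
  if (is.null(h2)) stop("no heritability supplied")
  h2d <- if (inherits(h2, "h2_posterior")) h2$draws else as.numeric(h2)
  if (length(h2d) == 1L) h2d <- rep(h2d, nrow(m))
  if (length(h2d) != nrow(m))
    stop("draw-count mismatch: ", length(h2d), " h2 draws vs ", nrow(m),
         " divergence draws")
  h2d <- pmin(pmax(h2d, 1e-12), 1)  # guard clipped-to-zero draws
  s2b <- m[, "sigma2_population"]
  # within-population phenotypic variance: every component except the
  # between-population one ("total"), or the residual alone
  s2w <- if (config$within == "total")
    rowSums(m[, setdiff(stream_chains$var_names, "sigma2_population"),
              drop = FALSE])
  else m[, "sigma2_resid"]
  draws <- pst_from_components(s2b, s2w, c = config$c, h2 = h2d)
  q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(stream = stream, draws = draws, median = q[2],
                 q025 = q[1], q975 = q[3],
                 fst_upper = config$fst_upper,
                 verdict = verdict_from_quantiles(q[1], q[3],
                                                  config$fst_upper)),
            class = "pst_posterior")
}

verdict_from_quantiles <- function(q025, q975, fst_upper) {
  if (q025 > fst_upper) "divergent"
  else if (q975 < fst_upper) "stabilizing"
  else "neutral"
}

#' Selection verdict from a P_ST posterior and a neutral F_ST reference
#'
#' Divergent selection is inferred when the whole 95\% credible interval
#' lies above the neutral reference (2.5\% quantile > \code{fst_upper});
#' stabilizing selection when it lies entirely below; otherwise the trait is
#' compatible with neutral divergence.
#'
#' @param pst A \code{\link{pst_posterior}}.
#' @param fst_upper Neutral reference; defaults to the value stored in the
#'   posterior.
#' @return \code{"divergent"}, \code{"stabilizing"} or \code{"neutral"}.
#' @export
compare_to_fst <- function(pst, fst_upper = NULL) {
  stopifnot(inherits(pst, "pst_posterior"))
  if (is.null(fst_upper)) fst_upper <- pst$fst_upper
  verdict_from_quantiles(pst$q025, pst$q975, fst_upper)
}

#' @export
print.pst_posterior <- function(x, ...) {
  cat(sprintf("P_ST posterior (%s): median %.3f [%.3f, %.3f] vs F_ST %.3f -> %s\n",
              x$stream, x$median, x$q025, x$q975, x$fst_upper, x$verdict))
  invisible(x)
}

#' Intraclass correlations from posterior variance draws
#'
#' Per retained draw, each variance component (including the residual) is
#' divided by the total of all components, so the fractions sum to one
#' exactly. Applied to the variance-partitioning model (random population,
#' stream and family with an intercept-only fixed part) this measures how
#' much of the phenotypic variation is attributable to population origin
#' versus rearing environment.
#'
#' @param chains A \code{posterior_chains}.
#' @return Object of class \code{icc_result}: \code{draws} (matrix, one
#'   column per component) and a summary data frame \code{summary} with
#'   medians and 95\% quantiles.
#' @export
icc <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  m <- as.matrix(chains)[, chains$var_names, drop = FALSE]
  draws <- m / rowSums(m)
  colnames(draws) <- sub("^sigma2_", "icc_", colnames(draws))
  smry <- data.frame(
    component = colnames(draws),
    median = apply(draws, 2, stats::median),
    q025 = apply(draws, 2, stats::quantile, 0.025),
    q975 = apply(draws, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(draws = draws, summary = smry), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("intraclass correlations (posterior):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Reaction-norm summary from the fixed-effect posterior
#'
#' Reconstructs the population-by-stream cell means per retained draw of
#' the reaction-norm model (fixed population, stream and interaction) and
#' summarises each cell with its median and 95\% credible interval. As a
#' scalar measure of parallelism it also reports, per draw, the ratio of
#' the spread (SD) of the interaction coefficients to the spread of the
#' population coefficients: near-zero ratios mean near-parallel norms.
#'
#' @param chains A \code{posterior_chains} whose fixed part includes
#'   population and stream.
#' @return List with \code{cells} (data frame: population, stream, median,
#'   q025, q975) and \code{parallelism} (draws + median and 95\% interval).
#' @export
reaction_norm_summary <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  if (!all(c("population", "stream") %in% chains$model$fixed))
    stop("reaction norms need fixed population and stream terms")
  grid <- expand.grid(population = chains$xlevels$population,
                      stream = chains$xlevels$stream,
                      stringsAsFactors = FALSE)
  gf <- grid
  gf$population <- factor(gf$population, levels = chains$xlevels$population)
  gf$stream <- factor(gf$stream, levels = chains$xlevels$stream)
  Xg <- stats::model.matrix(chains$fixed_formula, gf)
  beta <- as.matrix(chains)[, chains$fixed_names, drop = FALSE]
  cell_draws <- beta %*% t(Xg)      # draws x cells
  cells <- cbind(grid, data.frame(
    median = apply(cell_draws, 2, stats::median),
    q025 = apply(cell_draws, 2, stats::quantile, 0.025),
    q975 = apply(cell_draws, 2, stats::quantile, 0.975)))
  pop_idx <- which(chains$assign == match("population", chains$term_labels))
  int_idx <- which(chains$assign == match("population:stream",
                                          chains$term_labels))
  parallelism <- NULL
  if (length(pop_idx) >= 1L) {
    # treatment contrasts: include the reference level's implicit zero
    sd_with_ref <- function(idx) {
      if (!length(idx)) return(rep(0, nrow(beta)))
      apply(cbind(0, beta[, idx, drop = FALSE]), 1, stats::sd)
    }
    sd_pop <- sd_with_ref(pop_idx)
    sd_int <- sd_with_ref(int_idx)
    ratio <- ifelse(sd_pop > 0, sd_int / sd_pop, NA_real_)
    parallelism <- list(
      draws = ratio,
      median = stats::median(ratio, na.rm = TRUE),
      q025 = stats::quantile(ratio, 0.025, na.rm = TRUE, names = FALSE),
      q975 = stats::quantile(ratio, 0.975, na.rm = TRUE, names = FALSE))
  }
  list(cells = cells, parallelism = parallelism)
}
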