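#' Specify a Gaussian linear mixed model for body length
#'
#' Terms are named columns of the phenotype table: \code{"population"},
#' \code{"stream"}, \code{"population:stream"} (fixed side) and
#' \code{"family"} (the parental cross), \code{"sire"}, \code{"dam"},
#' \code{"population"}, \code{"stream"} (random side). The intercept is
#' always fixed; a term cannot appear on both sides.
#'
#' Common presets:
#' \itemize{
#'   \item reaction-norm model: fixed population, stream and interaction,
#'     random family;
#'   \item divergence model (per stream): random population and family;
#'   \item variance-partitioning model: random population, stream, family;
#'   \item diallel heritability model: random sire and dam.
#' }
#'
#' @param fixed Character vector of fixed terms (may be empty for an
#'   intercept-only fixed part).
#' @param random Character vector of random terms.
#' @param response Response column, default \code{"length"}.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(fixed = character(), random = "family",
                       response = "length") {
  fixed_ok <- c("population", "stream", "population:stream")
  random_ok <- c("family", "sire", "dam", "population", "stream")
  if (length(fixed) && !all(fixed %in% fixed_ok))
    stop("unknown fixed terms: ", paste(setdiff(fixed, fixed_ok), collapse = ", "))
  if (!all(random %in% random_ok))
    stop("unknown random terms: ", paste(setdiff(random, random_ok), collapse = ", "))
  clash <- intersect(fixed, random)
  if (length(clash))
    stop("terms cannot be both fixed and random: ", paste(clash, collapse = ", "))
  if ("population:stream" %in% fixed &&
      !all(c("population", "stream") %in% fixed))
    stop("an interaction requires both main effects on the fixed side")
  structure(list(fixed = fixed, random = random, response = response),
            class = "model_spec")
}

#' MCMC regime for the Gibbs sampler
#'
#' @param n_chains Number of parallel chains.
#' @param n_iter Iterations per chain.
#' @param n_burnin Iterations discarded at the start of each chain
#'   (must be < \code{n_iter}).
#' @param thin Keep every \code{thin}-th post-burn-in iteration; the
#'   retained count per chain is \code{floor((n_iter - n_burnin) / thin)}.
#' @param seed Root seed; chain \code{c} draws from its own substream
#'   seeded with \code{seed + 7919 * c}.
#' @return Object of class \code{mcmc_spec}.
#' @seealso \code{\link{mcmc_preset}} for the published and desk-scale
#'   regimes.
#' @export
mcmc_spec <- function(n_chains = 4L, n_iter = 20000L, n_burnin = 5000L,
                      thin = 10L, seed = 1L) {
  if (n_burnin >= n_iter) stop("'n_burnin' must be smaller than 'n_iter'")
  if (any(c(n_chains, n_iter, thin) < 1)) stop("counts must be positive")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_spec")
}

#' @rdname mcmc_spec
#' @param name \code{"paper"} for the published regime (6 chains of two
#'   million iterations, 800,000 burn-in, thinning 800: 9,000 retained
#'   draws) or \code{"desk"} for a reduced regime suited to interactive use
#'   (4 chains of 20,000, burn-in 5,000, thinning 10: 6,000 retained).
#' @export
mcmc_preset <- function(name = c("desk", "paper"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         paper = mcmc_spec(6L, 2000000L, 800000L, 800L, seed = seed),
         desk = mcmc_spec(4L, 20000L, 5000L, 10L, seed = seed))
}

#' Retained posterior draws implied by an MCMC regime
#' @param spec An \code{\link{mcmc_spec}}.
#' @param per_chain If \code{TRUE} return the per-chain count.
#' @export
retained_draws <- function(spec, per_chain = FALSE) {
  stopifnot(inherits(spec, "mcmc_spec"))
  per <- (spec$n_iter - spec$n_burnin) %/% spec$thin
  if (per_chain) per else spec$n_chains * per
}

random_col <- c(family = "cross_id", sire = "sire_id", dam = "dam_id",
                population = "population", stream = "stream")

# Drop included factor terms that have a single level in this subset
# (per-stream subsetting routinely degenerates the stream factor).
prune_terms <- function(model, data) {
  lv <- function(col) length(unique(data[[col]]))
  fixed <- model$fixed
  for (tm in c("population", "stream")) {
    if (tm %in% fixed && lv(tm) < 2L) {
      warning("dropping single-level fixed term '", tm, "'")
      fixed <- setdiff(fixed, c(tm, "population:stream"))
    }
  }
  random <- model$random
  for (tm in random) {
    if (lv(random_col[[tm]]) < 2L) {
      warning("dropping single-level random term '", tm, "'")
      random <- setdiff(random, tm)
    }
  }
  model_spec(fixed = fixed, random = random, response = model$response)
}

# Assemble y, dense X, random-effect index blocks and bookkeeping.
build_model_matrices <- function(data, model) {
  if (!nrow(data)) stop("empty phenotype table")
  y <- data[[model$response]]
  if (!is.numeric(y) || any(!is.finite(y))) stop("response must be finite numeric")
  model <- prune_terms(model, data)
  for (tm in model$random) {
    col <- random_col[[tm]]
    if (is.null(data[[col]])) stop("data lacks column '", col,
                                   "' needed for random term '", tm, "'")
  }
  fixed_formula <- if (length(model$fixed))
    stats::reformulate(model$fixed) else ~1
  mf_data <- data
  for (col in c("population", "stream"))
    if (!is.null(mf_data[[col]])) mf_data[[col]] <- factor(mf_data[[col]])
  X <- stats::model.matrix(fixed_formula, mf_data)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design (confounded factors)")
  xlevels <- list(population = levels(mf_data$population),
                  stream = levels(mf_data$stream))
  Zs <- lapply(model$random, function(tm) {
    f <- factor(data[[random_col[[tm]]]])
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- paste0(tm, ":", levels(f))
    Z
  })
  names(Zs) <- model$random
  W <- do.call(cbind, c(list(X), Zs))
  p <- ncol(X)
  sizes <- vapply(Zs, ncol, 0L)
  ends <- p + cumsum(sizes)
  starts <- ends - sizes + 1L
  blocks <- Map(function(s, e) s:e, starts, ends)
  names(blocks) <- model$random
  list(model = model, y = y, X = X, W = W, fixed_idx = seq_len(p),
       blocks = blocks, fixed_formula = fixed_formula, xlevels = xlevels,
       assign = attr(X, "assign"),
       term_labels = attr(stats::terms(fixed_formula), "term.labels"))
}

#' Fit a Gaussian linear mixed model by blocked Gibbs sampling
#'
#' Bayesian fit of \eqn{y = X\beta + \sum_r Z_r u_r + e} with
#' \eqn{u_r \sim N(0, \sigma^2_r I)} and \eqn{e \sim N(0, \sigma^2_e I)}.
#' Priors: flat (improper) on \eqn{\beta}; inverse-gamma(shape = 1e-3,
#' rate = 1e-3) on every variance, a locally uninformative choice.
#'
#' Full conditionals (each iteration):
#' \itemize{
#'   \item all location effects \eqn{\theta = (\beta, u)} jointly:
#'     \eqn{\theta | \sigma^2 \sim N(C^{-1} W'y/\sigma^2_e, C^{-1})} with
#'     \eqn{C = W'W/\sigma^2_e + diag(0, 1/\sigma^2_r)}, sampled via the
#'     Cholesky factor of \eqn{C} (a single blocked update, which keeps
#'     autocorrelation of the thinned draws near zero);
#'   \item \eqn{\sigma^2_r | u_r \sim} InvGamma(a + q_r/2, b + u_r'u_r/2);
#'   \item \eqn{\sigma^2_e | \theta \sim} InvGamma(a + n/2, b + RSS/2).
#' }
#' Only \eqn{W'W}, \eqn{W'y} and \eqn{y'y} are touched per iteration, so the
#' cost is independent of the number of records.
#'
#' Factors reduced to one level by subsetting are dropped with a warning.
#'
#' @param data Phenotype table (see \code{\link{read_phenotypes}}).
#' @param model A \code{\link{model_spec}}.
#' @param mcmc An \code{\link{mcmc_spec}}.
#' @return Object of class \code{posterior_chains}: per-chain matrices of
#'   retained draws (columns: fixed-effect coefficients, one
#'   \code{sigma2_<term>} per random term, and \code{sigma2_resid}).
#' @export
gibbs_fit <- function(data, model, mcmc = mcmc_spec()) {
  stopifnot(inherits(model, "model_spec"), inherits(mcmc, "mcmc_spec"))
  mm <- build_model_matrices(data, model)
  y <- mm$y
  W <- mm$W
  n <- length(y)
  P <- ncol(W)
  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)
  a0 <- b0 <- 1e-3  # inverse-gamma shape/rate: locally uninformative
  blocks <- mm$blocks
  nblk <- length(blocks)
  var_names <- c(if (nblk) paste0("sigma2_", names(blocks)), "sigma2_resid")
  par_names <- c(colnames(W)[mm$fixed_idx], var_names)
  keep_per <- retained_draws(mcmc, per_chain = TRUE)
  chains <- vector("list", mcmc$n_chains)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) vy <- 1
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 7919L * ch)
    draws <- matrix(NA_real_, keep_per, length(par_names),
                    dimnames = list(NULL, par_names))
    s2r <- rep(vy / 2, nblk)            # random-term variances
    s2e <- vy / 2                       # residual variance
    kept <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      # -- location effects, one joint blocked draw
      C <- WtW / s2e
      d <- numeric(P)
      for (k in seq_len(nblk)) d[blocks[[k]]] <- 1 / s2r[k]
      diag(C) <- diag(C) + d
      R <- chol(C)
      mu <- backsolve(R, backsolve(R, Wty / s2e, transpose = TRUE))
      theta <- mu + backsolve(R, stats::rnorm(P))
      # -- random-term variances
      for (k in seq_len(nblk)) {
        u <- theta[blocks[[k]]]
        s2r[k] <- 1 / stats::rgamma(1L, a0 + length(u) / 2,
                                    b0 + sum(u^2) / 2)
      }
      # -- residual variance
      rss <- max(yty - 2 * sum(theta * Wty) + drop(crossprod(theta, WtW %*% theta)),
                 0)
      s2e <- 1 / stats::rgamma(1L, a0 + n / 2, b0 + rss / 2)
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0L &&
          kept < keep_per) {
        kept <- kept + 1L
        draws[kept, ] <- c(theta[mm$fixed_idx], s2r, s2e)
      }
    }
    chains[[ch]] <- draws
  }
  structure(list(chains = chains, par_names = par_names,
                 fixed_names = colnames(W)[mm$fixed_idx],
                 var_names = var_names, model = mm$model, mcmc = mcmc,
                 fixed_formula = mm$fixed_formula, xlevels = mm$xlevels,
                 assign = mm$assign, term_labels = mm$term_labels,
                 n_records = n),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("posterior_chains: %d chains x %d retained draws, %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$par_names)))
  cat("parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

#' Pool retained draws over chains into one matrix
#' @param x A \code{posterior_chains} object.
#' @param ... Unused.
#' @export
as.matrix.posterior_chains <- function(x, ...) do.call(rbind, x$chains)

#' Posterior summary of a fitted model
#' @param object A \code{posterior_chains} object.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @export
summary.posterior_chains <- function(object, probs = c(0.025, 0.5, 0.975),
                                     ...) {
  m <- as.matrix(object)
  data.frame(parameter = colnames(m), mean = colMeans(m),
             t(apply(m, 2, stats::quantile, probs = probs)),
             row.names = NULL, check.names = FALSE)
}

#' Fit the same mixed model by REML (via lme4)
#'
#' Restricted maximum likelihood fit of the model in
#' \code{\link{model_spec}}, used as an independent check on
#' \code{\link{gibbs_fit}}: posterior means of variance components should
#' agree closely with the REML estimates on well-sized data.
#'
#' @inheritParams gibbs_fit
#' @return List with \code{fixed} (named coefficient vector),
#'   \code{variances} (named, same \code{sigma2_*} convention as the Gibbs
#'   chains) and the underlying \code{lme4} fit as \code{fit}.
#' @export
reml_fit <- function(data, model) {
  stopifnot(inherits(model, "model_spec"))
  mm_model <- prune_terms(model, data)
  if (!length(mm_model$random))
    stop("reml_fit requires at least one random term")
  for (col in c("population", "stream"))
    if (!is.null(data[[col]])) data[[col]] <- factor(data[[col]])
  fixed_part <- if (length(mm_model$fixed))
    paste(mm_model$fixed, collapse = " + ") else "1"
  rand_part <- paste(sprintf("(1 | %s)", random_col[mm_model$random]),
                     collapse = " + ")
  form <- stats::as.formula(paste(mm_model$response, "~", fixed_part, "+",
                                  rand_part))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  col_to_term <- stats::setNames(names(random_col), random_col)
  vars <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "sigma2_resid",
                                          paste0("sigma2_", col_to_term[vc$grp])))
  list(fixed = lme4::fixef(fit), variances = vars, fit = fit)
}

#' Narrow-sense heritability from posterior variance draws
#'
#' Per retained draw: in full-sib mode the family variance is taken as half
#' the additive variance, \code{h2 = 2 sigma2_family / (sigma2_family +
#' sigma2_resid)}; in diallel mode \code{V_A = 2 (sigma2_sire +
#' sigma2_dam)} divided by the within-population phenotypic variance.
#' A \code{sigma2_population} term, if present, is excluded from the
#' denominator (within-population heritability). Draws above 1 are clipped
#' to 1 and the clipped fraction reported.
#'
#' @param chains A \code{posterior_chains} with the needed variance terms.
#' @param mode \code{"fullsib"} or \code{"diallel"}.
#' @return Object of class \code{h2_posterior}: list with \code{draws},
#'   \code{mode}, \code{n_clipped}.
#' @export
estimate_h2 <- function(chains, mode = c("fullsib", "diallel")) {
  stopifnot(inherits(chains, "posterior_chains"))
  mode <- match.arg(mode)
  m <- as.matrix(chains)
  vn <- chains$var_names
  need <- if (mode == "fullsib") "sigma2_family" else c("sigma2_sire", "sigma2_dam")
  if (!all(need %in% vn))
    stop("chains lack variance terms for mode '", mode, "': ",
         paste(setdiff(need, vn), collapse = ", "))
  denom_terms <- setdiff(vn, "sigma2_population")
  denom <- rowSums(m[, denom_terms, drop = FALSE])
  va <- if (mode == "fullsib") 2 * m[, "sigma2_family"]
        else 2 * (m[, "sigma2_sire"] + m[, "sigma2_dam"])
  h2 <- va / denom
  n_clipped <- sum(h2 > 1)
  h2 <- pmin(pmax(h2, 0), 1)
  structure(list(draws = h2, mode = mode, n_clipped = n_clipped),
            class = "h2_posterior")
}

#' @export
print.h2_posterior <- function(x, ...) {
  q <- stats::quantile(x$draws, c(0.025, 0.5, 0.975))
  cat(sprintf("h2 posterior (%s): median %.3f [%.3f, %.3f], %d draws clipped\n",
              x$mode, q[2], q[1], q[3], x$n_clipped))
  invisible(x)
}
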