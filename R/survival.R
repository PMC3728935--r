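#' Standardised draw size for the survival bootstrap
#'
#' The bootstrap redraws every family at a common egg number (the cutoff)
#' so that unequal stocking does not bias population comparisons. The
#' cutoff is the smallest egg count at which a family is expected to yield
#' at least one survivor under the grand-mean survival rate: the smallest
#' integer \code{n} with \code{n * p >= 1}, where \code{p} is total
#' recaptures over total eggs across the supplied records.
#'
#' @param records Survival data frame (see \code{\link{read_survival}}),
#'   usually restricted to the natural streams of one experiment.
#' @return Integer cutoff.
#' @examples
#' r <- data.frame(cross_id = "x", population = "A", stream = "s",
#'                 n_stocked = 1000L, n_recaptured = 10L)
#' auto_cutoff(r)  # 100
#' @export
auto_cutoff <- function(records) {
  tot_rec <- sum(records$n_recaptured)
  tot_eggs <- sum(records$n_stocked)
  if (tot_eggs <= 0 || tot_rec <= 0)
    stop("cutoff undefined: no recaptures in the records")
  p <- tot_rec / tot_eggs
  n <- floor(1 / p + 1e-9)  # guard: 1/0.004 must give 250, not 251
  if (n * p >= 1 - 1e-9) n else n + 1L
}

#' Drop families stocked below the cutoff
#'
#' Families whose stocked egg number is below the cutoff (expected
#' survivors under the grand mean < 1) are discarded before resampling.
#'
#' @param records Survival data frame.
#' @param cutoff Integer cutoff (see \code{\link{auto_cutoff}}).
#' @return List with \code{records} (retained rows) and \code{n_excluded}.
#' @export
filter_families <- function(records, cutoff) {
  if (cutoff < 1) stop("'cutoff' must be >= 1")
  keep <- records$n_stocked >= cutoff
  list(records = records[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Parametric bootstrap of family-level binomial survival
#'
#' For each retained family, survival is summarised by
#' \code{p_hat = n_recaptured / n_stocked}. Each bootstrap replicate draws
#' a pseudo-survivor count \code{k ~ Binomial(cutoff, p_hat)} per family,
#' converts it to a pseudo-proportion \code{k / cutoff}, and averages the
#' family pseudo-proportions (unweighted) within each population and
#' stream. Confidence intervals are the empirical 2.5\% and 97.5\%
#' quantiles over replicates; population differences are computed per
#' replicate so their CIs account for the paired resampling. Results are
#' invariant to the row order of \code{records} and reproducible from
#' \code{seed}.
#'
#' @param records Survival data frame, already filtered (see
#'   \code{\link{filter_families}}); every (population, stream) cell must
#'   retain at least one family.
#' @param n_reps Bootstrap replicates (the conventional choice is 1000).
#' @param cutoff Standardised draw size per family; \code{"auto"} applies
#'   \code{\link{auto_cutoff}} to \code{records}.
#' @param seed Integer seed.
#' @param n_excluded Exclusion count carried into the report (bookkeeping
#'   from \code{\link{filter_families}}).
#' @return Object of class \code{survival_bootstrap}: \code{populations}
#'   (data frame with point estimate and CI per population and stream),
#'   \code{pairs} (per-stream pairwise difference CIs, overlap and
#'   contains-zero flags), \code{replicates} (list of replicate matrices by
#'   stream), plus \code{cutoff}, \code{n_reps}, \code{n_excluded}.
#' @export
bootstrap_survival <- function(records, n_reps = 1000L, cutoff = "auto",
                               seed = 1L, n_excluded = 0L) {
  if (!nrow(records)) stop("no families left to bootstrap")
  if (identical(cutoff, "auto")) cutoff <- auto_cutoff(records)
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  # canonical order: results must not depend on input row order
  ord <- order(records$stream, records$population, records$cross_id)
  records <- records[ord, , drop = FALSE]
  set.seed(seed)
  pop_rows <- NULL
  pair_rows <- NULL
  replicates <- list()
  for (stream in unique(records$stream)) {
    rs <- records[records$stream == stream, , drop = FALSE]
    pops <- unique(rs$population)
    rep_means <- matrix(NA_real_, n_reps, length(pops),
                        dimnames = list(NULL, pops))
    for (pop in pops) {
      rp <- rs[rs$population == pop, , drop = FALSE]
      phat <- rp$n_recaptured / rp$n_stocked
      nf <- length(phat)
      # replicate x family pseudo-proportions
      k <- matrix(stats::rbinom(n_reps * nf, cutoff, rep(phat, each = n_reps)),
                  n_reps, nf)
      rep_means[, pop] <- rowMeans(k / cutoff)
    }
    replicates[[stream]] <- rep_means
    est <- vapply(pops, function(pop) {
      rp <- rs[rs$population == pop, , drop = FALSE]
      mean(rp$n_recaptured / rp$n_stocked)
    }, 0)
    qs <- apply(rep_means, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
    pop_rows <- rbind(pop_rows, data.frame(
      stream = stream, population = pops, n_families =
        as.integer(table(rs$population)[pops]),
      estimate = unname(est), q025 = qs[1, ], q975 = qs[2, ],
      row.names = NULL))
    if (length(pops) > 1L) {
      cmb <- utils::combn(pops, 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        d <- rep_means[, a] - rep_means[, b]
        dq <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
        ova <- qs[, a]; ovb <- qs[, b]
        pair_rows <- rbind(pair_rows, data.frame(
          stream = stream, pop_a = a, pop_b = b,
          diff = mean(d), diff_q025 = dq[1], diff_q975 = dq[2],
          contains_zero = dq[1] <= 0 && dq[2] >= 0,
          ci_overlap = ova[1] <= ovb[2] && ovb[1] <= ova[2],
          row.names = NULL))
      }
    }
  }
  structure(list(populations = pop_rows, pairs = pair_rows,
                 replicates = replicates, cutoff = as.integer(cutoff),
                 n_reps = as.integer(n_reps),
                 n_excluded = as.integer(n_excluded)),
            class = "survival_bootstrap")
}

#' @export
print.survival_bootstrap <- function(x, ...) {
  cat(sprintf("survival bootstrap: cutoff %d eggs, %d replicates, %d families excluded\n",
              x$cutoff, x$n_reps, x$n_excluded))
  print(x$populations, row.names = FALSE, digits = 3)
  invisible(x)
}
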