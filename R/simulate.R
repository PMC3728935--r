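#' Parameters of the synthetic-data generator
#'
#' Defines the generative model mirrored by the fitted mixed models: body
#' length is
#' \deqn{y = \mu + pop + stream + pop:stream + family + e}
#' with the family term either a single full-sib effect
#' (\code{sigma2_family}) or a sire + dam decomposition in diallel mode
#' (\code{sigma2_sire}, \code{sigma2_dam}, optionally plus a cross-specific
#' \code{sigma2_family}). Survival is binomial per family and stream.
#'
#' Defaults emulate the study conditions: young-of-the-year trout around
#' 100 mm; population shifts with variance about 4 mm^2 so that phenotypic
#' divergence sits in the strongly divergent regime (P_ST roughly 0.5);
#' modest stream (plasticity) effects; essentially parallel reaction norms
#' (zero interaction); family variance 1 and residual variance 4 mm^2
#' (h^2 = 0.4); recapture probability 0.004 in natural streams and 0.08 in
#' the predator-free experimental stream.
#'
#' @param mu Grand mean length (mm).
#' @param pop_effects Named numeric vector of per-population shifts (mm).
#' @param stream_effects Named numeric vector of per-stream shifts (mm).
#' @param interaction_effects Matrix (populations x streams) of
#'   population-by-stream shifts, or \code{NULL} for none.
#' @param sigma2_family Full-sib family variance (cross-specific in diallel
#'   mode).
#' @param sigma2_sire,sigma2_dam Parental variances (diallel mode only).
#' @param sigma2_resid Residual variance.
#' @param survival_p Binomial recapture probability: a scalar, a named
#'   vector by stream, or a matrix (populations x streams).
#' @param seed Root seed for all draws.
#' @return Object of class \code{sim_params}.
#' @export
sim_params <- function(mu = 100,
                       pop_effects = c(Dalalven2 = 2.5, Dalalven8 = 1.5,
                                       Norumsan = 0, Avaan = -1.5,
                                       Jorlandaan = -2.5),
                       stream_effects = c(experimental = 0, Molnboan = -1,
                                          Brattasbacken = 1),
                       interaction_effects = NULL,
                       sigma2_family = 1,
                       sigma2_sire = 0, sigma2_dam = 0,
                       sigma2_resid = 4,
                       survival_p = c(experimental = 0.08, Molnboan = 0.004,
                                      Brattasbacken = 0.004),
                       seed = 1L) {
  vars <- c(sigma2_family = sigma2_family, sigma2_sire = sigma2_sire,
            sigma2_dam = sigma2_dam, sigma2_resid = sigma2_resid)
  if (any(vars < 0)) stop("variances must be non-negative")
  if (any(unlist(survival_p) < 0 | unlist(survival_p) > 1))
    stop("survival probabilities must lie in [0, 1]")
  structure(list(mu = mu, pop_effects = pop_effects,
                 stream_effects = stream_effects,
                 interaction_effects = interaction_effects,
                 sigma2_family = sigma2_family, sigma2_sire = sigma2_sire,
                 sigma2_dam = sigma2_dam, sigma2_resid = sigma2_resid,
                 survival_p = survival_p, seed = as.integer(seed)),
            class = "sim_params")
}

lookup_effect <- function(tab, key, what) {
  if (is.null(tab) || !length(tab)) return(0)
  if (is.null(names(tab))) stop(what, " effects must be named")
  if (!key %in% names(tab)) stop("no ", what, " effect for key: ", key)
  unname(tab[[key]])
}

lookup_interaction <- function(mat, pop, stream) {
  if (is.null(mat)) return(0)
  if (!pop %in% rownames(mat) || !stream %in% colnames(mat))
    stop("no interaction effect for (", pop, ", ", stream, ")")
  mat[pop, stream]
}

lookup_survival <- function(p, pop, stream) {
  if (is.matrix(p)) {
    if (!pop %in% rownames(p) || !stream %in% colnames(p))
      stop("no survival probability for (", pop, ", ", stream, ")")
    return(p[pop, stream])
  }
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (!stream %in% names(p))
    stop("no survival probability for stream: ", stream)
  unname(p[[stream]])
}

#' Simulate phenotype records for a stocked breeding design
#'
#' Draws one family (or sire and dam) effect per cross/parent, then for each
#' stocking entry draws the number of surviving juveniles and their body
#' lengths from the generative model in \code{\link{sim_params}}. Survival
#' and growth are independent. Fully reproducible from \code{params$seed}.
#'
#' @param design A \code{\link{breeding_design}}.
#' @param plan A \code{\link{build_stocking}} plan; every cross in the plan
#'   must exist in the design.
#' @param params A \code{\link{sim_params}} object.
#' @param survivors Either \code{"binomial"} (draw survivor counts from the
#'   survival model) or a single non-negative integer used for every
#'   (cross, stream) entry, decoupling phenotype simulation from binomial
#'   survival noise.
#' @param mode \code{"fullsib"} (one family effect per cross) or
#'   \code{"diallel"} (sire + dam effects, plus a cross effect if
#'   \code{sigma2_family > 0}).
#' @return A phenotype data frame (see \code{\link{read_phenotypes}}),
#'   including \code{sire_id}/\code{dam_id} columns.
#' @export
simulate_phenotypes <- function(design, plan, params,
                                survivors = "binomial",
                                mode = c("fullsib", "diallel")) {
  stopifnot(inherits(design, "breeding_design"),
            inherits(plan, "stocking_plan"),
            inherits(params, "sim_params"))
  mode <- match.arg(mode)
  unknown <- setdiff(plan$cross_id, design$crosses$cross_id)
  if (length(unknown))
    stop("plan references crosses absent from design: ",
         paste(unknown, collapse = ", "))
  set.seed(params$seed)
  cr <- design$crosses
  # one effect per cross / parent, shared across streams
  if (mode == "fullsib") {
    fam_eff <- stats::rnorm(nrow(cr), 0, sqrt(params$sigma2_family))
    names(fam_eff) <- cr$cross_id
    genetic <- fam_eff[cr$cross_id]
  } else {
    sires <- unique(cr$sire_id)
    dams <- unique(cr$dam_id)
    sire_eff <- stats::setNames(stats::rnorm(length(sires), 0,
                                             sqrt(params$sigma2_sire)), sires)
    dam_eff <- stats::setNames(stats::rnorm(length(dams), 0,
                                            sqrt(params$sigma2_dam)), dams)
    cross_eff <- stats::rnorm(nrow(cr), 0, sqrt(params$sigma2_family))
    genetic <- sire_eff[cr$sire_id] + dam_eff[cr$dam_id] + cross_eff
    names(genetic) <- cr$cross_id
  }
  pop_of <- stats::setNames(cr$population, cr$cross_id)
  sire_of <- stats::setNames(cr$sire_id, cr$cross_id)
  dam_of <- stats::setNames(cr$dam_id, cr$cross_id)
  recs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cross <- plan$cross_id[i]
    stream <- plan$stream[i]
    pop <- pop_of[[cross]]
    n <- if (identical(survivors, "binomial")) {
      stats::rbinom(1L, plan$n_eggs[i],
                    lookup_survival(params$survival_p, pop, stream))
    } else {
      if (!is.numeric(survivors) || length(survivors) != 1L || survivors < 0)
        stop("'survivors' must be \"binomial\" or one non-negative integer")
      as.integer(survivors)
    }
    if (n == 0L) next
    mean_i <- params$mu +
      lookup_effect(params$pop_effects, pop, "population") +
      lookup_effect(params$stream_effects, stream, "stream") +
      lookup_interaction(params$interaction_effects, pop, stream) +
      genetic[[cross]]
    recs[[i]] <- data.frame(
      individual_id = sprintf("%s-%s-%03d", cross, stream, seq_len(n)),
      cross_id = cross, population = pop, stream = stream,
      experiment = design$experiment,
      length = mean_i + stats::rnorm(n, 0, sqrt(params$sigma2_resid)),
      sire_id = sire_of[[cross]], dam_id = dam_of[[cross]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(individual_id = character(), cross_id = character(),
                      population = character(), stream = character(),
                      experiment = integer(), length = numeric(),
                      sire_id = character(), dam_id = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate family-level survival records
#'
#' Each stocking entry yields \code{n_recaptured ~ Binomial(n_eggs, p)} with
#' \code{p} looked up per (population, stream); draws are independent across
#' families and reproducible from \code{params$seed}.
#'
#' @inheritParams simulate_phenotypes
#' @return A survival data frame (see \code{\link{read_survival}}).
#' @export
simulate_survival <- function(plan, params) {
  stopifnot(inherits(plan, "stocking_plan"), inherits(params, "sim_params"))
  design <- attr(plan, "design")
  pop_of <- stats::setNames(design$crosses$population, design$crosses$cross_id)
  set.seed(params$seed + 1L)  # distinct substream from phenotype draws
  p <- vapply(seq_len(nrow(plan)), function(i)
    lookup_survival(params$survival_p, pop_of[[plan$cross_id[i]]],
                    plan$stream[i]), 0)
  data.frame(cross_id = plan$cross_id, population = pop_of[plan$cross_id],
             stream = plan$stream, n_stocked = plan$n_eggs,
             n_recaptured = stats::rbinom(nrow(plan), plan$n_eggs, p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ground-truth divergence quantities implied by simulation parameters
#'
#' Converts generator parameters into the quantities the analysis estimates:
#' the between-population variance \code{sigma2_B} (empirical variance of the
#' population shifts, denominator k - 1), the within-population phenotypic
#' variance \code{sigma2_W}, the narrow-sense heritability implied by the
#' family structure, and the phenotypic divergence index at truth.
#'
#' Heritability conventions match \code{\link{estimate_h2}}: a full-sib
#' family variance is half the additive variance, so
#' \code{h2 = 2 sigma2_family / (sigma2_family + sigma2_resid)}; in diallel
#' mode \code{V_A = 2 (sigma2_sire + sigma2_dam)} and the denominator is the
#' full within-population phenotypic variance.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param c Proportion of between-population variance assumed additive.
#' @param mode \code{"fullsib"} or \code{"diallel"}.
#' @return List with \code{true_sigma2_B}, \code{true_sigma2_W},
#'   \code{true_h2}, \code{true_pst}.
#' @export
ground_truth <- function(params, c = 1, mode = c("fullsib", "diallel")) {
  stopifnot(inherits(params, "sim_params"))
  mode <- match.arg(mode)
  s2b <- stats::var(as.numeric(params$pop_effects))
  if (mode == "fullsib") {
    s2w <- params$sigma2_family + params$sigma2_resid
    h2 <- if (s2w > 0) 2 * params$sigma2_family / s2w else 0
  } else {
    s2w <- params$sigma2_sire + params$sigma2_dam + params$sigma2_family +
      params$sigma2_resid
    h2 <- if (s2w > 0) 2 * (params$sigma2_sire + params$sigma2_dam) / s2w else 0
  }
  h2 <- min(h2, 1)
  pst <- if (s2b == 0) 0
         else if (h2 == 0) 1  # no additive variance within: all divergence
         else pst_from_components(s2b, s2w, c = c, h2 = h2)
  list(true_sigma2_B = s2b, true_sigma2_W = s2w, true_h2 = h2,
       true_pst = pst)
}
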