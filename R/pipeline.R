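#' Assemble and validate a pipeline run configuration
#'
#' A run configuration ties together the breeding design, stocking plan,
#' simulation parameters (or paths to phenotype/survival CSV files), the
#' model/MCMC regime, the divergence configuration and the bootstrap
#' settings. Validation problems are collected and reported all at once.
#'
#' @param design A \code{\link{breeding_design}}.
#' @param stocking A \code{\link{build_stocking}} plan.
#' @param params A \code{\link{sim_params}} object, or \code{NULL} when
#'   \code{phenotypes_path}/\code{survival_path} point at real tables.
#' @param phenotypes_path,survival_path Optional CSV inputs used instead of
#'   simulation.
#' @param mcmc An \code{\link{mcmc_spec}} (the per-model seed is derived
#'   from the run seed).
#' @param pst A \code{\link{pst_config}}.
#' @param mode \code{"fullsib"} or \code{"diallel"} heritability mode.
#' @param n_boot_reps,boot_cutoff Bootstrap replicates and cutoff
#'   (\code{"auto"} or integer).
#' @param experimental_stream Label of the semi-natural stream: used for
#'   the heritability fit and excluded from the survival analysis.
#' @param out_dir Output directory (\code{NULL} for no file output).
#' @param seed Root seed fanned out to the simulate / fit / bootstrap
#'   stages.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(design, stocking, params = NULL,
                       phenotypes_path = NULL, survival_path = NULL,
                       mcmc = mcmc_spec(), pst = pst_config(),
                       mode = c("fullsib", "diallel"),
                       n_boot_reps = 1000L, boot_cutoff = "auto",
                       experimental_stream = "experimental",
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  probs <- character()
  if (!inherits(design, "breeding_design"))
    probs <- c(probs, "'design' is not a breeding_design")
  if (!inherits(stocking, "stocking_plan"))
    probs <- c(probs, "'stocking' is not a stocking_plan")
  if (is.null(params) && is.null(phenotypes_path))
    probs <- c(probs, "either 'params' or 'phenotypes_path' is required")
  if (!is.null(params) && !inherits(params, "sim_params"))
    probs <- c(probs, "'params' is not a sim_params object")
  for (p in c(phenotypes_path, survival_path))
    if (!is.null(p) && !file.exists(p))
      probs <- c(probs, paste0("input path does not exist: ", p))
  if (!inherits(mcmc, "mcmc_spec")) probs <- c(probs, "'mcmc' is not an mcmc_spec")
  if (!inherits(pst, "pst_config")) probs <- c(probs, "'pst' is not a pst_config")
  if (n_boot_reps < 1) probs <- c(probs, "'n_boot_reps' must be >= 1")
  if (length(probs))
    stop("invalid run configuration:\n  ", paste(probs, collapse = "\n  "))
  structure(list(design = design, stocking = stocking, params = params,
                 phenotypes_path = phenotypes_path,
                 survival_path = survival_path, mcmc = mcmc, pst = pst,
                 mode = mode, n_boot_reps = as.integer(n_boot_reps),
                 boot_cutoff = boot_cutoff,
                 experimental_stream = experimental_stream,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

with_mcmc_seed <- function(mcmc, seed) {
  mcmc_spec(mcmc$n_chains, mcmc$n_iter, mcmc$n_burnin, mcmc$thin, seed = seed)
}

#' Run the full divergence pipeline
#'
#' Stages, mirroring the analysis workflow: (1) simulate or load phenotype
#' and survival tables; (2) fit the reaction-norm model (fixed population,
#' stream, interaction; random family) on all data; (3) fit the
#' variance-partitioning model (random population, stream, family) for
#' intraclass correlations; (4) per stream, fit the divergence model
#' (random population + family), estimate heritability from the
#' experimental-stream fit, and form the P_ST posterior and its verdict
#' against the neutral F_ST reference; (5) bootstrap survival over the
#' natural streams. A failed per-stream fit is logged and marked, not
#' fatal. Everything is deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{run_config}}.
#' @param verbose Print stage progress to stderr.
#' @return Object of class \code{run_report} with elements
#'   \code{pst} (per-stream summary data frame), \code{pst_posteriors},
#'   \code{icc}, \code{reaction_norms}, \code{survival},
#'   \code{diagnostics}, \code{ground_truth} (when simulated),
#'   \code{provenance}.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[qstream] ", sprintf(...))
  seed <- config$seed

  # -- stage 1: data
  if (!is.null(config$phenotypes_path)) {
    say("loading phenotypes from %s", config$phenotypes_path)
    pheno <- read_phenotypes(config$phenotypes_path)
    truth <- NULL
  } else {
    say("simulating phenotypes (seed %d)", seed)
    params <- config$params
    params$seed <- seed
    pheno <- simulate_phenotypes(config$design, config$stocking, params,
                                 mode = config$mode)
    truth <- ground_truth(params, c = config$pst$c, mode = config$mode)
  }
  surv <- if (!is.null(config$survival_path)) {
    read_survival(config$survival_path)
  } else if (!is.null(config$params)) {
    params <- config$params
    params$seed <- seed
    simulate_survival(config$stocking, params)
  } else NULL

  # -- stage 2: reaction-norm model
  say("fitting reaction-norm model")
  m1 <- gibbs_fit(pheno,
                  model_spec(fixed = c("population", "stream",
                                       "population:stream"),
                             random = "family"),
                  with_mcmc_seed(config$mcmc, seed + 100L))
  rn <- reaction_norm_summary(m1)
  diag_m1 <- mcmc_diagnostics(m1)

  # -- stage 3: variance partitioning (ICC)
  say("fitting variance-partitioning model")
  micc <- gibbs_fit(pheno,
                    model_spec(fixed = character(),
                               random = c("population", "stream", "family")),
                    with_mcmc_seed(config$mcmc, seed + 200L))
  icc_res <- icc(micc)
  diag_icc <- mcmc_diagnostics(micc)

  # -- stage 4: per-stream divergence + heritability
  streams <- unique(pheno$stream)
  div_model <- if (config$mode == "diallel")
    model_spec(fixed = character(), random = c("population", "sire", "dam"))
  else model_spec(fixed = character(), random = c("population", "family"))
  fits <- list()
  for (i in seq_along(streams)) {
    s <- streams[i]
    say("fitting divergence model for stream %s", s)
    fits[[s]] <- tryCatch(
      gibbs_fit(pheno[pheno$stream == s, , drop = FALSE], div_model,
                with_mcmc_seed(config$mcmc, seed + 300L + i)),
      error = function(e) {
        warning("divergence fit failed for stream ", s, ": ",
                conditionMessage(e))
        NULL
      })
  }
  exp_stream <- config$experimental_stream
  h2 <- NULL
  if (!is.null(fits[[exp_stream]]))
    h2 <- estimate_h2(fits[[exp_stream]], mode = config$mode)
  pst_list <- list()
  for (s in streams) {
    if (is.null(fits[[s]]) || is.null(h2)) next
    pst_list[[s]] <- pst_posterior(fits[[s]], h2 = h2, config = config$pst,
                                   stream = s)
  }
  pst_tab <- if (length(pst_list)) do.call(rbind, lapply(pst_list, function(p)
    data.frame(stream = p$stream, median = p$median, q025 = p$q025,
               q975 = p$q975, verdict = p$verdict, row.names = NULL)))
  else NULL
  diag_div <- lapply(fits[!vapply(fits, is.null, TRUE)], mcmc_diagnostics)

  # -- stage 5: survival bootstrap (natural streams only)
  surv_res <- NULL
  if (!is.null(surv)) {
    nat <- surv[surv$stream != exp_stream, , drop = FALSE]
    if (nrow(nat) && sum(nat$n_recaptured) > 0) {
      say("bootstrapping survival over %d natural-stream families", nrow(nat))
      cutoff <- if (identical(config$boot_cutoff, "auto")) auto_cutoff(nat)
                else as.integer(config$boot_cutoff)
      flt <- filter_families(nat, cutoff)
      if (nrow(flt$records)) {
        surv_res <- bootstrap_survival(flt$records,
                                       n_reps = config$n_boot_reps,
                                       cutoff = cutoff, seed = seed + 500L,
                                       n_excluded = flt$n_excluded)
      } else say("all families below cutoff; skipping survival bootstrap")
    } else say("no natural-stream recaptures; skipping survival bootstrap")
  }

  all_diag <- c(list(reaction_norm = diag_m1, icc = diag_icc), diag_div)
  diagnostics <- list(
    per_model = lapply(all_diag, function(d)
      list(psrf_q975 = d$psrf_q975, max_abs_acf = d$max_abs_acf)),
    psrf_q975 = max(vapply(all_diag, `[[`, 0, "psrf_q975")),
    max_abs_acf = max(vapply(all_diag, `[[`, 0, "max_abs_acf")))

  report <- structure(list(
    pst = pst_tab, pst_posteriors = pst_list, h2 = h2, icc = icc_res,
    reaction_norms = rn, survival = surv_res, diagnostics = diagnostics,
    ground_truth = truth,
    provenance = list(seed = seed,
                      mcmc = unclass(config$mcmc),
                      package_version = as.character(utils::packageVersion("qstream")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, pheno, surv)
  report
}

write_report <- function(report, out_dir, pheno = NULL, surv = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(pheno)) write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
  if (!is.null(surv)) write_survival(surv, file.path(out_dir, "survival.csv"))
  if (!is.null(report$pst))
    utils::write.table(report$pst, file.path(out_dir, "pst_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$icc$summary, file.path(out_dir, "icc_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$survival)) {
    utils::write.table(report$survival$populations,
                       file.path(out_dir, "survival_populations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$survival$pairs))
      utils::write.table(report$survival$pairs,
                         file.path(out_dir, "survival_pairs.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(report_payload(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Machine-comparable payload of a run report
#'
#' Strips the report down to plain lists/data frames (draws and timestamps
#' removed) so that two runs with the same seed serialize identically.
#'
#' @param report A \code{run_report}.
#' @export
report_payload <- function(report) {
  list(
    pst = report$pst,
    h2 = if (!is.null(report$h2))
      list(median = stats::median(report$h2$draws),
           q025 = stats::quantile(report$h2$draws, 0.025, names = FALSE),
           q975 = stats::quantile(report$h2$draws, 0.975, names = FALSE),
           n_clipped = report$h2$n_clipped),
    icc = report$icc$summary,
    reaction_norms = list(cells = report$reaction_norms$cells,
                          parallelism =
                            report$reaction_norms$parallelism[c("median",
                                                                "q025", "q975")]),
    survival = if (!is.null(report$survival))
      list(populations = report$survival$populations,
           pairs = report$survival$pairs,
           cutoff = report$survival$cutoff,
           n_excluded = report$survival$n_excluded),
    diagnostics = report$diagnostics,
    ground_truth = report$ground_truth,
    seed = report$provenance$seed)
}

#' @export
print.run_report <- function(x, ...) {
  cat("qstream run report (seed ", x$provenance$seed, ")\n", sep = "")
  if (!is.null(x$pst)) {
    cat("\nP_ST by stream:\n")
    print(x$pst, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$h2)) print(x$h2)
  cat("\n"); print(x$icc)
  cat(sprintf("\ndiagnostics: Gelman-Rubin 97.5%% quantile %.4f, max |acf| %.4f\n",
              x$diagnostics$psrf_q975, x$diagnostics$max_abs_acf))
  if (!is.null(x$survival)) { cat("\n"); print(x$survival) }
  if (!is.null(x$ground_truth))
    cat(sprintf("\nsimulation truth: P_ST %.3f, h2 %.3f\n",
                x$ground_truth$true_pst, x$ground_truth$true_h2))
  invisible(x)
}
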