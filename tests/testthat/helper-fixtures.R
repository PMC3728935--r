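# Shared fixture builders; everything is generated in code at test time.

five_pop_design <- function(n_pairs = 12) {
  build_design(lapply(paste0("P", 1:5), function(nm) pop_spec(nm, n_pairs)),
               experiment = 1)
}

five_pop_params <- function(seed = 1, sigma2_family = 1, sigma2_resid = 4,
                            streams = c(experimental = 0)) {
  sim_params(mu = 100,
             pop_effects = c(P1 = 2.5, P2 = 1.5, P3 = 0, P4 = -1.5,
                             P5 = -2.5),
             stream_effects = streams,
             sigma2_family = sigma2_family, sigma2_resid = sigma2_resid,
             seed = seed)
}

# Hand-built posterior_chains holding given draw matrices, for exercising
# the posterior statistics without running the sampler.
fake_chains <- function(..., fixed_names = character()) {
  mats <- list(...)
  par_names <- colnames(mats[[1]])
  structure(list(chains = mats, par_names = par_names,
                 fixed_names = fixed_names,
                 var_names = setdiff(par_names, fixed_names),
                 model = model_spec(random = "family"),
                 mcmc = mcmc_spec(length(mats), 2, 1, 1),
                 n_records = 0L),
            class = "posterior_chains")
}
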