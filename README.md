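# qstream

Quantitative-genetic divergence analysis for multi-population,
multi-stream common-garden experiments on salmonids (and similar designs
in other organisms).

## The problem

When families from several locally adapted populations are reared together
across several environments, two questions drive the analysis:

1. **Is trait divergence among populations adaptive?** The standardised
   divergence of a quantitative trait,

   Q<sub>ST</sub> = σ²<sub>AB</sub> / (σ²<sub>AB</sub> + 2 σ²<sub>AW</sub>),

   is compared with neutral marker differentiation F<sub>ST</sub>:
   Q<sub>ST</sub> ≫ F<sub>ST</sub> indicates divergent selection,
   Q<sub>ST</sub> ≪ F<sub>ST</sub> stabilizing selection. When survival is
   too low to estimate additive variances in every environment, the
   phenotypic proxy (Brommer's P<sub>ST</sub>) is used instead:

   P<sub>ST</sub> = c σ²<sub>B</sub> / (c σ²<sub>B</sub> + 2 h² σ²<sub>W</sub>),

   with σ²<sub>B</sub> the between-population and σ²<sub>W</sub> the
   within-population phenotypic variance, c the fraction of the
   between-population variance assumed additive (conventionally 1) and h²
   the narrow-sense heritability estimated in the best-surviving
   environment.

2. **How much phenotypic variation is genetic versus plastic?** Intraclass
   correlations ICC<sub>X</sub> = σ²<sub>X</sub> / σ²<sub>S</sub> partition
   the total variance between population origin, rearing environment,
   family and residual.

`qstream` implements the full workflow: breeding-design constructors
(unique-pair full-sib and incomplete 2×2 diallel), a synthetic-data
generator with known ground truth, a blocked Gibbs sampler for the
Gaussian linear mixed models (flat priors on fixed effects, locally
uninformative inverse-gamma priors on variances) with Gelman–Rubin and
autocorrelation diagnostics and an lme4 REML cross-check, posterior
P<sub>ST</sub>/ICC/heritability computation, reaction-norm parallelism
summaries, and a parametric bootstrap for family-level binomial survival
designed for very low recapture rates (standardised draw sizes via an
expected-one-survivor cutoff).

## Worked example

Simulate a four-population experiment stocked into one semi-natural and
two natural streams, then run the whole pipeline (a reduced MCMC regime
keeps this example fast):

```r
library(qstream)

design <- build_design(lapply(paste0("P", 1:4),
                              function(nm) pop_spec(nm, n_pairs = 8)),
                       experiment = 1)
params <- sim_params(
  mu = 100, pop_effects = c(P1 = 2.5, P2 = 1, P3 = -1, P4 = -2.5),
  stream_effects = c(experimental = 0, nat1 = -1, nat2 = 1),
  sigma2_family = 1, sigma2_resid = 4,
  survival_p = c(experimental = 0.3, nat1 = 0.05, nat2 = 0.05))
plan <- build_stocking(design, list(experimental = 60, nat1 = 300, nat2 = 300))

cfg <- run_config(design, plan, params,
                  mcmc = mcmc_spec(2, 3000, 1000, 5),
                  pst = pst_config(c = 1, fst_upper = 0.1),
                  n_boot_reps = 500, seed = 7)
report <- run_pipeline(cfg)
report
```

```
qstream run report (seed 7)

P_ST by stream:
       stream median  q025  q975   verdict
 experimental  0.605 0.239 0.946 divergent
         nat1  0.573 0.227 0.938 divergent
         nat2  0.552 0.190 0.938 divergent
h2 posterior (fullsib): median 0.404 [0.233, 0.671], 0 draws clipped

intraclass correlations (posterior):
      component median    q025  q975
 icc_population 0.4509 0.09803 0.908
     icc_stream 0.0994 0.00999 0.709
     icc_family 0.0637 0.00887 0.156
      icc_resid 0.2911 0.04249 0.558

diagnostics: Gelman-Rubin 97.5% quantile 1.0144, max |acf| 0.1819

survival bootstrap: cutoff 20 eggs, 500 replicates, 0 families excluded
 stream population n_families estimate   q025   q975
   nat1         P1          8   0.0554 0.0250 0.0938
   ...

simulation truth: P_ST 0.547, h2 0.400
```

Reading the output: the generator was configured with a true
P<sub>ST</sub> of 0.547 and true h² of 0.400; the per-stream posterior
medians (0.55–0.61) and the heritability posterior (median 0.404) recover
both, and every 95% credible interval lies above the neutral reference
F<sub>ST</sub> = 0.1, so body length is called divergent in all three
streams. Population origin explains more variance (ICC 0.45) than rearing
stream (0.10), i.e. adaptive divergence overrides plasticity. The
survival bootstrap finds no population differences — the data were
simulated with equal survival.

The published design constants are available directly:
`study_design(1)` (57 full-sib families; 11,400 eggs at 200/family) and
`study_design(2)` (90 diallel crosses; 9,000 eggs at 100/family), and
`mcmc_preset("paper")` is the six-chain, two-million-iteration regime that
retains 9,000 draws.

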