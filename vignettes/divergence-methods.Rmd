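---
title: "Methods: divergence, variance partitioning and survival in multi-stream common gardens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, variance partitioning and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstream)
```

## Scope and model

`qstream` analyses experiments in which full-sib (or diallel) families
from several populations are reared together in several stream
environments, with body length at the end of the first growth season as
the focal trait and egg-to-recapture survival as a fitness component.
All length models are Gaussian linear mixed models,

$$y_{ijk} = \mu + \text{pop}_i + \text{stream}_j +
(\text{pop:stream})_{ij} + u_{f(k)} + e_{ijk},$$

with terms moved between the fixed and random side depending on the
question:

* **Reaction-norm model** — fixed population, stream and interaction;
  random family. Used for cell means and the parallelism summary.
* **Divergence model** (per stream) — random population and family.
  Its population variance is the between-population component
  $\sigma^2_B$ entering the divergence index.
* **Variance-partitioning model** — random population, stream and
  family with an intercept-only fixed part; its components are
  normalised into intraclass correlations.
* **Heritability model** — random population and family (full-sib) or
  sire and dam (diallel), fitted on the best-surviving environment.

### Divergence index

Per retained posterior draw $t$,

$$P_{ST}^{(t)} = \frac{c\,\sigma^{2(t)}_B}
{c\,\sigma^{2(t)}_B + 2 h^{2(t)} \sigma^{2(t)}_W},$$

with $c \in (0,1]$ the assumed additive fraction of the
between-population variance (default 1, the conventional choice) and
$h^{2(t)}$ a heritability draw paired by index. With equal MCMC regimes
the index pairing is a valid Monte-Carlo approximation of two
independent posteriors. The verdict against the neutral reference
`fst_upper` (the upper 95% quantile of marker F\_ST, supplied by the
user, not estimated here) is *divergent* if the 2.5% quantile of the
$P_{ST}$ posterior exceeds it, *stabilizing* if the 97.5% quantile falls
below it, and *neutral* otherwise.

Two conventions were genuinely open and are settled as follows:

* $\sigma^2_W$ defaults to the **total** within-population phenotypic
  variance (family + residual components); a `within = "residual-only"`
  switch is provided because the verbal gloss of $\sigma^2_W$ as
  "residual variation" admits either reading. Using the total is the
  conservative choice (it can only lower $P_{ST}$).
* $\sigma^2_B$ is taken from a **random**-population model rather than
  from the spread of fixed population coefficients; with only 4–6
  populations the random-effect route propagates the (large)
  uncertainty in the between-population variance into the
  $P_{ST}$ posterior instead of treating the observed spread as known.

### Heritability

Full-sib family variance is treated as half the additive variance
($\sigma^2_{fam} = \tfrac12 V_A$), so
$h^2 = 2\sigma^2_{fam} / (\sigma^2_{fam} + \sigma^2_{resid})$;
dominance and common-environment contributions to the family variance
are knowingly ignored (the $c$ parameter separately absorbs
non-additivity between populations). In diallel mode
$V_A = 2(\sigma^2_{sire} + \sigma^2_{dam})$ over the full
within-population phenotypic variance. A population variance component,
when present, is excluded from the denominator: the quantity is
within-population heritability. Draws above 1 are clipped to 1 and the
clipped count reported; on well-specified fits the clip fraction is
far below 1%.

### Intraclass correlations

Per draw, each variance component (including the residual) is divided
by the sum of all components, so the fractions sum to one exactly. The
model includes a family random term in addition to population and
stream: siblings are not independent, and omitting the term would
inflate the population component. This is a deliberate deviation risk
relative to descriptions that name only population and stream.

## Sampler, priors, diagnostics

`gibbs_fit()` is a blocked Gibbs sampler. All location effects
$(\beta, u)$ are drawn jointly from their multivariate-normal full
conditional via the Cholesky factor of
$C = W'W/\sigma^2_e + \mathrm{diag}(0, 1/\sigma^2_r)$; each variance is
then drawn from its inverse-gamma full conditional. Because only
$W'W$, $W'y$ and $y'y$ are touched per iteration, cost is independent
of the record count, and the joint location update keeps the lag-1
autocorrelation of thinned draws near zero.

Priors: flat (improper) on fixed effects; inverse-gamma with shape and
rate $10^{-3}$ on every variance — a standard "locally uninformative"
choice. The data always dominate at the sample sizes considered here;
with a truly null variance component the posterior piles up near zero
(its 2.5% quantile falls below 1% of the residual variance, a property
tested in the suite).

Reproducibility: chain $c$ is seeded with `seed + 7919 * c`, so chains
are independent streams and every fit is bit-reproducible.

Convergence is reported as the 97.5% quantile across parameters of the
Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ (accept $< 1.2$) and the maximum
absolute lag-1 autocorrelation of the retained draws across parameters
and chains (accept $\le 0.1$). A constant chain raises an error in
`autocorr()` rather than silently returning 0. The published regime — 6
chains × 2,000,000 iterations, 800,000 burn-in, thinning 800, i.e.
9,000 retained draws — is available as `mcmc_preset("paper")`; desk
work and the test suite use reduced regimes (typically 4 × 20,000,
burn-in 5,000, thin 10) which already satisfy both bounds on the
simulated designs.

`reml_fit()` fits the identical model by REML through `lme4` and serves
as an independent oracle: posterior means of variance components agree
with REML estimates within 10% on simulated datasets of moderate size
(50 families × 20 offspring), mirroring the congruence check customary
for these models.

## Survival bootstrap

Recapture rates in natural streams are of order $10^{-3}$–$10^{-2}$ with
heavily skewed egg allocations, which defeats binomial/Poisson GLMs.
The parametric bootstrap standardises families to a common draw size:
the cutoff is the smallest egg number whose expected survivor count
under the grand-mean survival reaches one (`ceiling(1/p)` with a
floating-point guard); families stocked below it are discarded and
counted. Each replicate draws
$k_f \sim \mathrm{Binomial}(\text{cutoff}, \hat p_f)$ per family,
averages $k_f/\text{cutoff}$ unweighted within population and stream
("population mean from family means"), and the 2.5%/97.5% quantiles over
1,000 replicates give the CIs. Population differences are computed per
replicate; both difference CIs and marginal CI-overlap flags are
reported, and no p-values are produced — inference is CI-based by
design. The semi-natural experimental stream is excluded by default:
its predator-free mortality regime differs qualitatively from the
natural streams. Results are invariant to record order (families are
canonically sorted before drawing) and reproducible from the seed.

Family proportions are kept per (family, stream) by default, since CIs
are reported within each natural stream; pooling across streams is a
flag away. Explicit cutoff overrides are accepted for reproducing
published analyses whose pooling convention is not recoverable from the
data at hand.

## The synthetic-data generator

`simulate_phenotypes()` / `simulate_survival()` generate data with
exactly the structure the models assume: Gaussian lengths built from a
grand mean, population/stream/interaction shifts, family (or
sire + dam) effects shared across streams, and i.i.d. residuals;
binomial survival independent of growth. `ground_truth()` converts any
parameter set into the implied $\sigma^2_B$ (empirical variance of the
population shifts, denominator $k-1$ — matching how a posterior over
population effects is summarised downstream), $\sigma^2_W$, $h^2$ and
$P_{ST}$, enabling recovery tests with known truth.

Default calibration (units: mm and mm², chosen once as realistic for
young-of-the-year brown trout of ~100 mm): population shifts
(±2.5, ±1.5, 0) giving $\sigma^2_B = 4.25$; family variance 1 and
residual 4, hence $h^2 = 0.4$ and a true $P_{ST} \approx 0.52$ — the
strongly divergent regime the method is meant to detect; stream shifts
of ±1 mm and zero interaction (near-parallel reaction norms); survival
0.004 in natural streams and 0.08 in the experimental stream, matching
the order of magnitude of observed recapture fractions. No published
effect-size scale exists for the trait, so these are documented
package choices, not estimates.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: maternal egg-size effects (confounded with
the dam/family variance in real designs), growth–survival correlation,
dispersal out of the study reach, size-selective predation,
non-Gaussian tails, and unequal within-population variances across
environments (the $P_{ST}$ machinery assumes the experimental-stream
heritability transfers to the other streams).

## Numerical and degenerate-input choices

* Retained-draw bookkeeping is exact integer arithmetic:
  `floor((n_iter - n_burnin)/thin)` per chain.
* Factors reduced to a single level by per-stream subsetting are
  dropped with a warning, not an error, so one degenerate stream does
  not abort a multi-stream run; a genuinely singular fixed design
  (confounded factors) errors.
* $P_{ST}$ with both variances zero is undefined and errors; heritability
  draws clipped to zero are floored at $10^{-12}$ inside the index so a
  single degenerate draw cannot produce 0/0.
* The residual sum of squares inside the sampler is floored at zero to
  absorb floating-point cancellation on near-noise-free data.
* Bootstrap CIs use empirical type-7 quantiles; families with
  $\hat p_f \in \{0, 1\}$ propagate to exact point CIs.

## Problem sizes used in the test suite

The suite runs every statistical claim at reduced scale, chosen so the
checks are sharp but quick: the diagnostics regime is verified on a
balanced 5 × 2 design with 3,600 records (4 chains × 20,000
iterations); $P_{ST}$ recovery uses 50 replicate simulations of
5 populations × 12 families × 30 offspring with 2 chains × 4,000
iterations each (95% credible intervals cover truth in ≥ 80% of
replicates, median bias < 0.1); the Gibbs-vs-REML congruence check uses
20 datasets of 50 families × 20 offspring (10% tolerance); the
bootstrap null check uses 100 seeded two-population runs at survival
0.004 (≥ 85 difference CIs containing zero). These sizes are package
choices balancing statistical resolution against runtime on a single
CPU.

## Known limitations

* No correction for the downward bias of Q\_ST-type estimators with few
  populations; with 4–6 populations estimates are conservative and
  intervals wide.
* F\_ST is a supplied scalar; no marker-based estimation.
* No animal-model/pedigree BLUP beyond the two supported designs, and
  no non-Gaussian survival GLMs (they do not converge at these
  survival rates — the bootstrap exists precisely for that regime).
* Single trait, single measurement occasion; no multivariate
  divergence.
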