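---
title: "Correcting matched case-control odds ratios for exposure measurement error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting matched case-control odds ratios for exposure measurement error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In individually matched case-control studies, each case is paired with one
or more controls on matching factors (here: maternal age and referring
physician in a study of serum perfluorinated-acid levels and maternal
hypothyroxinemia), and association is estimated by conditional logistic
regression, which eliminates the stratum-specific intercepts. When the
continuous exposures are laboratory measurements, they carry random assay
error. Ignoring that error attenuates the odds ratios toward the null and
understates uncertainty. `matchedme` fits a joint Bayesian model that
corrects multiple continuous exposures for classical additive measurement
error within the matched design, alongside the naive comparator that
pretends the measurements are exact.

## The model

For subject $j$ of matched set $i$ ($i = 1,\dots,N$, $j = 1,\dots,n_i$, the
case labelled $j = 1$) with latent true exposures
$X_{ij} \in \mathbb{R}^P$, observed surrogates $W_{ij}$, and precisely
measured confounders $Z_{ij} \in \mathbb{R}^K$:

* **Measurement model** (classical, non-differential, unbiased):
  $W_{ij} \mid X_{ij} \sim N_P(X_{ij}, \Sigma)$ with
  $\Sigma = \mathrm{diag}(\sigma^2_1,\dots,\sigma^2_P)$ treated as known.
  Because exposures are analysed on the log-molar scale, additive error
  there is multiplicative error on the concentration scale, the usual
  behaviour of assay error for positive analytes.
* **Disease model** (conditional logistic): with
  $\eta_{ij} = X_{ij}^\top\beta + Z_{ij}^\top\delta$,
  $$\log L(\beta,\delta) \;=\; \sum_{i=1}^{N}
    \Big( \eta_{i1} - \log \sum_{j=1}^{n_i} e^{\eta_{ij}} \Big).$$
  $e^{\beta_p}$ is the odds ratio per unit of exposure $p$;
  $e^{\delta_k}$ per unit of confounder $k$.
* **Exposure model** (two-level random effects): set means
  $M_i \sim N_P(\mu, V_B)$ and members $X_{ij} \sim N_P(M_i, V_W)$, with
  $V_W$ common across sets. Acknowledging both between- and within-set
  variation in the exposures is what licenses keeping the conditional
  likelihood as the disease model when $X$ is latent; the same two-level
  structure is used by the synthetic-data generator, so inference and
  generation share one law.
* **Priors**: $\beta_p, \delta_k \sim N(0, 10^4)$;
  $V_W^{-1}, V_B^{-1} \sim W_P(R, b)$ with inverse scale $R = I_P$ and
  $b = P$ degrees of freedom, the minimal proper choice; all overridable in
  `prior_spec()`. The grand mean $\mu$ is a plug-in constant, the mean of
  the matched-set means of the observed surrogates (`default_prior()`), so
  sets of unequal size weigh equally; an explicit value can be supplied
  instead.

Confounders enter the disease model only. They are deliberately left out of
the exposure model: in the motivating setting exposure-confounder
correlations are small (below 0.18), so they contribute little to
reconstructing the latent exposures, and omitting them keeps the conjugate
structure. A matching variable may also appear as a confounder (age in the
default generator); the package does not deduplicate.

## Error variances from percent-recovery QC data

The assay's error variance is identified from a spike-recovery experiment:
a pooled serum sample measured unspiked ($c$, say in ppb) and spiked
($c + a$, spike $a$ = 50 ppb), plus a gold standard of the spike alone.
The percent recovery is $Q = (\text{spiked} - \text{unspiked})/\text{gold}$.
Under lognormal assay error with log-scale variance $\sigma^2$ applied
identically and independently to all three measurements, a first-order
delta expansion of $Q$ around zero error gives

$$\mathrm{Var}(Q) \;\approx\; \sigma^2 \, g(c, a), \qquad
  g(c,a) = \Big(\frac{c}{a}\Big)^2 + \Big(\frac{c+a}{a}\Big)^2 + 1,$$

so `estimate_sigma2()` returns $\hat\sigma^2 = s_Q^2 / g(c, a)$ from the
recovery SD $s_Q$ (a fraction, e.g. 0.157, not a percentage). The gradient
is evaluated at the error mean (zero), the standard first-order choice.
`simulate_recovery()` is the built-in Monte-Carlo oracle for this
approximation; the tests require agreement within 5% for
$\sigma \le 0.2$ and $c/a \le 3$. $c$ defaults to the across-sample mean
concentration when a study table is available, otherwise it is a user
input. $\Sigma$ is then held fixed in the posterior; propagating its
uncertainty would need richer validation data (replicates, a validation
subsample) than a recovery experiment provides.

## Sampling

`run_mcmc()` is a Metropolis-within-Gibbs sampler (compiled core) with the
sweep: (1) each $M_i$ from its conjugate multivariate-normal full
conditional; (2) $V_W^{-1}$, $V_B^{-1}$ from conjugate Wishart full
conditionals; (3) each $X_{ij}$ by random-walk Metropolis against the
measurement + disease + exposure terms, with a per-coordinate proposal
shaped like the conditional scale
$(1/\sigma^2_p + (V_W^{-1})_{pp})^{-1/2}$ — this keeps proposals sensible
from strong error ($\Sigma$ large) down to the near-degenerate
$\Sigma \to 0$ limit; (4) $(\beta, \delta)$ jointly by random-walk
Metropolis with a diagonal proposal whose per-coordinate scales are
estimated on the fly, repeated several times per sweep
(`n_bd_updates`, default 5) since this block is far cheaper than the
latent-exposure block and the log ORs are the quantities whose Monte Carlo
error matters.

Step sizes adapt by Robbins–Monro toward 0.35 acceptance during burn-in
only and are frozen afterwards, so the retained draws come from a
fixed-kernel chain. The defaults mirror the analysis protocol the method
was developed under: 2 chains × 55,000 iterations, 5,000 burn-in, no
thinning, convergence read from split-chain R-hat and batch-means MCSE.
Chain 1 starts at the observed data ($X = W$, empirical set means and
covariances regularized to positive definite, $\beta = \delta = 0$);
later chains are deterministically offset (+0.5 on coefficients,
inflated covariances) to start dispersed. The naive fit uses the same
machinery with $X \equiv W$ fixed and only block (4) active.

Degenerate inputs are rejected at load time: every set needs exactly one
case and at least two members (a case with no control would contribute
nothing to the conditional likelihood while leaving its latent exposures
disease-uninformed), and a zero error variance is redirected to the naive
fit rather than silently degenerating the measurement model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `beta_var`, `delta_var` | $10^4$ | prior variance of each log OR (log-OR$^2$ units) |
| `wishart_R`, `wishart_df` | $I_P$, $P$ | inverse scale / df of both precision priors |
| `mu` | set-mean average | plug-in exposure grand mean (log-molar units) |
| `n_iter`, `n_burn`, `n_chains` | 55000, 5000, 2 | chain geometry |
| `n_bd_updates` | 5 | $(\beta,\delta)$ Metropolis repeats per sweep |
| `scale_factor` | 1 | multiplier on all $\sigma^2_p$ (sensitivity sweeps) |

## The synthetic-data generator

`simulate_study()` draws data with exactly the structure the model assumes,
shaped like the motivating study: $N = 96$ matched sets
(21 of size 2, 71 of size 3, 4 of size 4 — 271 subjects; the
real composition is unpublished beyond its total, so one composition was
fixed once), $P = 3$ log-scale exposures with the two-level normal
structure ($V_W = V_B$ with variance 0.35 and pairwise correlation 0.3,
giving a total log-scale SD of about 0.84, a realistic 2–3-fold
geometric spread), $K = 4$ confounders (age-like with matching-induced
within-set clustering, weight-like, a binary race-like indicator,
gestational-age-like) loading weakly on the set-level exposure deviations
so all exposure-confounder correlations stay under 0.18. The case within
each set is drawn with probability proportional to
$\exp(X_{ij}^\top\beta + Z_{ij}^\top\delta)$ — exactly the law the
conditional likelihood describes, so no sets are discarded — and the
surrogate is $W = X + U$ with $U$ drawn independently of case status
(non-differential by construction). Default effect sizes
$\beta = (\log 0.9, \log 0.8, \log 1.3)$ sit in the weak-effect regime
where attenuation matters; default error variances put the error SD at
30% of the total exposure SD (moderate error; the motivating assay's
fitted $\Sigma$ is not recoverable because the mean concentrations behind
it are unpublished). `censor_study()` adds limit-of-detection censoring on
the concentration scale for exercising the LOD/2 + log-molar preprocessing
path.

What the generator does *not* emulate: skewed or mixture-distributed
exposures, differential or systematic assay error, missing data beyond
non-detects, and frequency-matched designs. Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation — with a misspecified
exposure distribution the corrected estimates can still be biased.

## Numerical choices

* Conditional-logistic terms use log-sum-exp stabilisation throughout.
* Natural logs everywhere; the log-molar transform is
  $x = \log(c / m_p)$ with $m_p$ the concentration-per-molar conversion
  factor, inverse of $c = m_p e^x$.
* Credible intervals are empirical 2.5%/97.5% quantiles of the pooled
  post-burn-in OR draws (R's default interpolated quantile); the posterior
  mean OR is the mean of $e^\beta$ draws, so it exceeds
  $e^{\text{mean}(\beta)}$ by Jensen's inequality — both are reported.
* R-hat is the split-chain potential scale reduction factor; MCSE is
  batch-means with $\lfloor\sqrt{n}\rfloor$-sized batches, combined across
  chains.
* Empirical covariance initial values are ridge-regularized to a minimum
  eigenvalue of $10^{-6}$.
* Wishart draws use the Bartlett decomposition; all randomness flows
  through R's RNG, so a `base_seed` makes the whole `ChainSet`
  bit-reproducible (chain $c$ seeds with `base_seed + c - 1`; sweep factor
  $k$ offsets by $1000k$).

## Small-sample behaviour worth knowing

With only a handful of matched sets and non-trivial error, the marginal
likelihood of $\beta$ does not decay as $|\beta| \to \infty$: the latent
exposures can always be perturbed slightly to make the case dominate, at a
bounded cost in the measurement and exposure terms. The flat tail's height
falls geometrically with the number of sets whose observed ordering
contradicts the effect direction, so at realistic study sizes (tens of
sets or more) the posterior is effectively proper long before the diffuse
prior matters — but on toy instances (say 5–20 sets) the $N(0, 10^4)$
prior lets chains wander into that tail. The package's tiny-instance
validation tests therefore pair the sampler with a deterministic
quadrature oracle under a moderately informative prior shared by both
routes. Users fitting very small studies should tighten `beta_var`
deliberately rather than rely on the default diffuseness.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: the
delta-method estimator against the Monte-Carlo recovery simulator ($10^6$
replicates); the conditional likelihood against exhaustive enumeration and
an independent Newton maximiser (and `survival::clogit`) at $N = 400$–500
sets; the conjugate Gibbs blocks against a plain R Gibbs sampler on the
one-exposure hierarchy; the full posterior on a 5-set single-exposure
instance against a grid × Gauss–Hermite quadrature oracle; the sampler's
running log posterior against the R-side `log_joint()` at the final state;
and the headline property — coverage of the generating log ORs by the
corrected 95% intervals — over 20 replicates of the default 96-set
scenario with 2 × 11,000-iteration chains, alongside one full-protocol
run at 2 × 55,000. Attenuation direction and interval widening are checked
over 10 replicates and a 1–10× error-scale sweep.

## Limitations

Beyond the generator's non-goals above: $\Sigma$ must be diagonal and
known (no error correlation across analytes, no uncertainty propagation);
confounders must be precisely measured; only one case per set is
supported; and no frequentist comparators (regression calibration, SIMEX,
conditional scores) are provided.
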