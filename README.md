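# matchedme

Bayesian correction for measurement error in multiple continuous exposures
in **individually matched case-control studies**.

Epidemiological exposures measured by laboratory assay — serum biomarker
concentrations, for instance — carry random error. In a matched
case-control design analysed by conditional logistic regression, ignoring
that error biases the odds ratios toward the null and understates their
uncertainty. `matchedme` fits the joint Bayesian model that corrects for
this: a conditional logistic **disease model** on latent true exposures
$X$, a classical additive **measurement model**
$W \mid X \sim N_P(X, \Sigma)$ with known diagonal error covariance on the
log scale, and a two-level random-effect **exposure model**
($M_i \sim N_P(\mu, V_B)$ between matched sets,
$X_{ij} \sim N_P(M_i, V_W)$ within), with diffuse normal priors on the log
odds ratios and Wishart priors on the precision matrices. Inference is by
a compiled Metropolis-within-Gibbs sampler with conjugate updates for the
set means and covariances.

The package also provides:

* `estimate_sigma2()` — the error variances $\sigma^2_p$ from
  percent-recovery QC experiments via the multivariate delta method
  ($\hat\sigma^2 = s_Q^2 / g(c, a)$, $g(c,a) = (c/a)^2 + ((c+a)/a)^2 + 1$),
  with `simulate_recovery()` as its Monte-Carlo check;
* `fit_naive()` — the error-ignoring comparator ($X \equiv W$);
* `sensitivity_sweep()` — refits across multiples of the assumed error
  variance (1–10×);
* `simulate_study()` / `censor_study()` — a generator for synthetic
  matched studies with exactly the model's structure (default: 96 sets of
  size 2–4, 271 subjects, 3 exposures, 4 confounders), including
  limit-of-detection censoring for the LOD/2 + log-molar preprocessing
  path (`apply_lod()`, `to_log_molar()`);
* broom-style `tidy()`/`glance()` and `autoplot()` methods, and a thin CLI
  (`inst/cli/matchedme`).

## Worked example

```r
library(matchedme)

# a synthetic matched study shaped like a serum-biomarker analysis:
# 96 sets (one case each, 1-3 controls), 3 log-scale exposures, 4 confounders
study <- simulate_study(seed = 11)
study
#> <matched_study> 96 sets, 271 subjects (96 cases), P=3 exposures, K=4 confounders

# error variances from a percent-recovery QC table
qc <- read_qc(system.file("extdata", "synthetic_recovery_qc.csv",
                          package = "matchedme"))
spec <- estimate_sigma2(qc)
spec
#> <me_spec> sigma^2 = 0.01181, 0.007738, 0.03099  (scale factor 1)

# corrected, confounder-adjusted fit (here with shortened chains)
fit <- fit_me(study, me_spec(attr(study, "truth")$sigma2),
              config = sampler_config(n_iter = 6000, n_burn = 1000,
                                      n_chains = 2, base_seed = 5))
tidy(fit)
#> # A tibble: 7 x 8
#>   term     estimate conf.low conf.high   log_or log_or_sd  rhat     mcse
#>   <chr>       <dbl>    <dbl>     <dbl>    <dbl>     <dbl> <dbl>    <dbl>
#> 1 pfoa        0.883    0.419     1.64  -0.185     0.349    1.01 0.0142
#> 2 pfos        0.987    0.578     1.59  -0.0473    0.262    1.00 0.00880
#> 3 pfhxs       1.11     0.611     1.86   0.0675    0.286    1.00 0.0109
#> 4 age         0.970    0.749     1.24  -0.0383    0.127    1.00 0.00397
#> 5 weight      0.989    0.978     1.000 -0.0111    0.00574  1.00 0.000112
#> 6 race        0.809    0.420     1.41  -0.259     0.306    1.00 0.00912
#> 7 gest_age    0.995    0.967     1.02  -0.00537   0.0140   1.00 0.000297
```

Each row is one coefficient: `estimate` is the posterior mean odds ratio
per unit of the (log-scale) exposure or confounder, `conf.low`/`conf.high`
the equal-tailed 95% credible interval, `log_or`/`log_or_sd` the posterior
mean and SD on the log-OR scale, and `rhat`/`mcse` the split-chain
Gelman-Rubin statistic and the batch-means Monte Carlo standard error
(values near 1 and well below 0.05 here: converged, precise enough for
two-decimal ORs). This study was generated with true ORs (0.9, 0.8, 1.3)
and null confounders — all seven intervals cover their truth. The
corresponding naive fit (`fit_naive(study, config = ...)`) gives slightly
narrower intervals and estimates slightly closer to 1: at this moderate
error level the correction is visible but small, and
`sensitivity_sweep(study, spec, factors = c(1, 2, 5, 10))` shows the
estimates moving away from the null and the intervals widening as the
assumed error grows. `autoplot()` on a fit draws the posterior OR
densities; on a sweep, the OR trajectories against the scale factor.

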