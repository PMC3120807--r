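#' Naive conditional-logistic Bayesian fit (error ignored)
#'
#' Fits the conditional logistic disease model treating the observed
#' surrogate exposures as if they were measured exactly (`X == W`): the
#' posterior is the conditional likelihood times the diffuse normal priors on
#' the log ORs, with no measurement or exposure-model terms. This is the
#' comparator whose estimates are attenuated toward the null when the
#' exposures actually carry error.
#'
#' @param study A `matched_study`.
#' @param use_confounders Adjust for the confounder columns (the "adjusted"
#'   model) or not (the "simple" model).
#' @param prior A [prior_spec()].
#' @param config A [sampler_config()].
#' @return An object of class `me_fit` (see [tidy.me_fit()], [glance.me_fit()]).
#' @export
fit_naive <- function(study, use_confounders = TRUE,
                      prior = default_prior(study),
                      config = sampler_config()) {
  t0 <- proc.time()[["elapsed"]]
  chains <- run_mcmc(study, spec = NULL, prior = prior, config = config,
                     use_confounders = use_confounders, naive = TRUE)
  new_me_fit(chains, mode = "naive", use_confounders = use_confounders,
             runtime = proc.time()[["elapsed"]] - t0)
}

#' Measurement-error-corrected Bayesian fit
#'
#' Fits the full joint model: conditional logistic disease model on latent
#' true exposures, classical normal measurement model with known diagonal
#' error covariance, and the two-level random-effect exposure model, by
#' Metropolis-within-Gibbs sampling (see [run_mcmc()]).
#'
#' @inheritParams fit_naive
#' @param spec An [me_spec()] with strictly positive error variances; a
#'   zero-variance spec is rejected with a pointer to [fit_naive()].
#' @return An object of class `me_fit`.
#' @export
fit_me <- function(study, spec, use_confounders = TRUE,
                   prior = default_prior(study),
                   config = sampler_config()) {
  stopifnot(inherits(spec, "me_spec"))
  if (any(spec$sigma2 <= 0)) {
    abort("spec has zero error variance: use fit_naive() for the error-free model")
  }
  t0 <- proc.time()[["elapsed"]]
  chains <- run_mcmc(study, spec = spec, prior = prior, config = config,
                     use_confounders = use_confounders, naive = FALSE)
  new_me_fit(chains, mode = "me", use_confounders = use_confounders,
             runtime = proc.time()[["elapsed"]] - t0)
}

new_me_fit <- function(chains, mode, use_confounders, runtime) {
  structure(list(chains = chains, mode = mode,
                 use_confounders = use_confounders,
                 summary = summarize_or(chains), runtime = runtime),
            class = "me_fit")
}

#' Summarise posterior odds ratios
#'
#' Pools the post-burn-in draws across chains and reports, per coefficient,
#' the posterior mean odds ratio `mean(exp(draws))`, the equal-tailed 95%
#' credible interval (empirical 2.5% and 97.5% quantiles of the OR draws),
#' the posterior mean and SD on the log-OR scale, the split-chain R-hat, and
#' the batch-means Monte Carlo standard error of the posterior log-OR mean.
#'
#' @param chains A `chain_set`.
#' @return A tibble with one row per coefficient: `term`, `estimate` (OR),
#'   `conf.low`, `conf.high`, `log_or`, `log_or_sd`, `rhat`, `mcse`.
#' @export
summarize_or <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  draws <- coef_draws(chains)
  if (nrow(draws[[1]]) == 0) abort("no post-burn-in draws")
  pooled <- do.call(rbind, draws)
  rhat <- if (chains$config$n_chains >= 2) gelman_rubin(chains) else
    setNames(rep(NA_real_, ncol(pooled)), colnames(pooled))
  mcses <- mcse(chains)
  tibble::tibble(
    term = colnames(pooled),
    estimate = unname(apply(exp(pooled), 2, mean)),
    conf.low = unname(apply(exp(pooled), 2, quantile, probs = 0.025)),
    conf.high = unname(apply(exp(pooled), 2, quantile, probs = 0.975)),
    log_or = unname(apply(pooled, 2, mean)),
    log_or_sd = unname(apply(pooled, 2, sd)),
    rhat = unname(rhat[colnames(pooled)]),
    mcse = unname(mcses[colnames(pooled)])
  )
}

#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("<me_fit> %s analysis (%s model), %d chain(s) x %d iterations\n",
              if (x$mode == "naive") "naive" else "measurement-error",
              if (x$use_confounders) "confounder-adjusted" else "simple",
              x$chains$config$n_chains, x$chains$config$n_iter))
  print(x$summary)
  invisible(x)
}

#' Tidy an `me_fit`
#'
#' @param x An `me_fit`.
#' @param ... Unused.
#' @return The per-coefficient OR summary tibble (see [summarize_or()]).
#' @exportS3Method generics::tidy
tidy.me_fit <- function(x, ...) x$summary

#' One-row fit summary
#'
#' @param x An `me_fit`.
#' @param ... Unused.
#' @return A one-row tibble: mode, model, chain geometry, worst R-hat and
#'   MCSE, acceptance rates, elapsed seconds.
#' @exportS3Method generics::glance
glance.me_fit <- function(x, ...) {
  cs <- x$chains
  tibble::tibble(
    mode = x$mode,
    adjusted = x$use_confounders,
    n_chains = cs$config$n_chains,
    n_iter = cs$config$n_iter,
    n_burn = cs$config$n_burn,
    max_rhat = max(x$summary$rhat),
    max_mcse = max(x$summary$mcse),
    accept_x = mean(vapply(cs$chains, function(c) c$accept_x, numeric(1))),
    accept_beta = mean(vapply(cs$chains, function(c) c$accept_beta, numeric(1))),
    elapsed = x$runtime
  )
}

#' Sensitivity sweep over the assumed error magnitude
#'
#' Refits the measurement-error model with the error covariance scaled by
#' each factor, mirroring the question "what if the assay error were k times
#' more variable than the QC experiment suggests?". Factors must be strictly
#' increasing and include 1 (the assumed magnitude). Each factor runs with
#' its own reproducible seed (`base_seed + 1000 * factor_index`); a failure
#' at one factor is recorded and the sweep continues.
#'
#' @inheritParams fit_me
#' @param factors Strictly increasing numeric vector in `(0, 10]`
#'   containing 1; default `c(1, 2, 5, 10)`.
#' @return A tibble of class `sensitivity_result`: the per-coefficient OR
#'   summary at each `scale_factor`, plus an `errors` attribute naming any
#'   failed factors.
#' @export
sensitivity_sweep <- function(study, spec, factors = c(1, 2, 5, 10),
                              use_confounders = TRUE,
                              prior = default_prior(study),
                              config = sampler_config()) {
  stopifnot(inherits(spec, "me_spec"))
  if (any(factors <= 0) || any(factors > 10)) {
    abort("factors must lie in (0, 10]")
  }
  if (is.unsorted(factors, strictly = TRUE)) {
    abort("factors must be strictly increasing")
  }
  if (!any(factors == 1)) abort("factors must include 1")
  rows <- list()
  errors <- character()
  for (idx in seq_along(factors)) {
    f <- factors[idx]
    cfg <- config
    cfg$base_seed <- config$base_seed + 1000L * idx
    res <- tryCatch(
      fit_me(study, scale_sigma2(spec, f), use_confounders = use_confounders,
             prior = prior, config = cfg),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors <- c(errors, setNames(conditionMessage(res), as.character(f)))
      next
    }
    rows[[length(rows) + 1]] <-
      dplyr::mutate(tidy(res), scale_factor = f, .before = 1)
  }
  structure(dplyr::bind_rows(rows),
            class = c("sensitivity_result", class(tibble::tibble())),
            errors = errors)
}

#' Fit the four standard models
#'
#' Runs the naive simple (N-S), naive adjusted (N-A), measurement-error
#' simple (ME-S) and measurement-error adjusted (ME-A) analyses on one study
#' and stacks their OR summaries into a comparison table.
#'
#' @inheritParams fit_me
#' @return A tibble with a `model` column (`"N-S"`, `"N-A"`, `"ME-S"`,
#'   `"ME-A"`) and the [summarize_or()] columns; the fitted objects are
#'   attached as the `fits` attribute.
#' @export
compare_models <- function(study, spec, prior = default_prior(study),
                           config = sampler_config()) {
  fits <- list(
    "N-S" = fit_naive(study, use_confounders = FALSE, prior = prior, config = config),
    "N-A" = fit_naive(study, use_confounders = TRUE, prior = prior, config = config),
    "ME-S" = fit_me(study, spec, use_confounders = FALSE, prior = prior, config = config),
    "ME-A" = fit_me(study, spec, use_confounders = TRUE, prior = prior, config = config)
  )
  out <- dplyr::bind_rows(
    lapply(fits, function(f) dplyr::mutate(tidy(f), .before = 1)),
    .id = "model"
  )
  attr(out, "fits") <- fits
  out
}
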