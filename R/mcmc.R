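#' Sampler configuration
#'
#' Defaults follow the protocol used for the motivating analysis: two chains
#' of 55,000 iterations with the first 5,000 discarded as burn-in and no
#' thinning. Random-walk step sizes are adapted (Robbins-Monro, targeting
#' 0.35 acceptance) during burn-in only and frozen afterwards, preserving
#' detailed balance in the retained draws.
#'
#' @param n_iter Iterations per chain (default 55000).
#' @param n_burn Burn-in iterations discarded from each chain (default 5000).
#' @param n_chains Number of chains (default 2).
#' @param base_seed Integer seed; chain `c` uses `base_seed + c - 1`.
#' @param adapt_window Iterations of step-size adaptation, `<= n_burn`.
#' @param step_x Initial random-walk scale for the latent-exposure block
#'   (multiplies a conditional-sd-shaped per-coordinate proposal).
#' @param step_b Initial random-walk scale for the joint `(beta, delta)`
#'   block (multiplies an adaptively estimated per-coordinate sd).
#' @param n_bd_updates Metropolis repeats of the `(beta, delta)` block per
#'   sweep; extra repeats are cheap and improve mixing of the log ORs.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_iter = 55000, n_burn = 5000, n_chains = 2,
                           base_seed = 1, adapt_window = n_burn,
                           step_x = 1, step_b = 1, n_bd_updates = 5) {
  stopifnot(n_burn < n_iter, n_chains >= 1, n_burn >= 0,
            adapt_window <= n_burn, step_x > 0, step_b > 0, n_bd_updates >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains),
                 base_seed = as.integer(base_seed),
                 adapt_window = as.integer(adapt_window),
                 step_x = step_x, step_b = step_b,
                 n_bd_updates = as.integer(n_bd_updates)),
            class = "sampler_config")
}

# initial state for chain `chain` (1-based). Chain 1 starts at the observed
# data (X = W, set means, empirical covariances, beta = delta = 0); later
# chains are deterministically offset so chains start dispersed.
mcmc_inits <- function(inp, prior, chain = 1) {
  W <- inp$W
  P <- ncol(W)
  grp <- rep(seq_along(inp$set_size), inp$set_size)
  M0 <- apply(W, 2, function(col) tapply(col, grp, mean))
  M0 <- matrix(M0, ncol = P)
  VW0 <- cov(W - M0[grp, , drop = FALSE]) * (nrow(W) - 1) /
    max(1, nrow(W) - nrow(M0))
  VB0 <- cov(M0)
  regularize <- function(V) {
    V <- (V + t(V)) / 2
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) V <- V + diag(1e-6 - min(ev, 0) + 1e-8, nrow(V))
    V
  }
  off <- 0.5 * (chain - 1)
  list(X = W, M = M0,
       VW = regularize(VW0) * 1.5^(chain - 1),
       VB = regularize(VB0) * 1.5^(chain - 1),
       beta = rep(off, P),
       delta = rep(off, ncol(inp$Z)))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Targets the joint posterior of the measurement-error model: per sweep it
#' (1) draws each set mean `M_i` from its conjugate multivariate normal full
#' conditional, (2) draws the within/between precision matrices from their
#' conjugate Wishart full conditionals, (3) updates each subject's latent
#' exposure vector by random-walk Metropolis against the measurement +
#' disease + exposure terms, and (4) updates `(beta, delta)` jointly by
#' random-walk Metropolis against the conditional-logistic likelihood and
#' priors. With `naive = TRUE` the latent structure is dropped (`X == W`
#' fixed) and only step (4) runs.
#'
#' @param study A `matched_study`.
#' @param spec An [me_spec()] with strictly positive variances (ignored when
#'   `naive = TRUE`).
#' @param prior A [prior_spec()]; defaults to [default_prior()] of the study.
#' @param config A [sampler_config()].
#' @param use_confounders Include the confounder columns in the disease
#'   model (`delta` block)?
#' @param naive Fit the error-ignoring comparator instead of the joint model.
#' @param fix_cov Optional list with `V_W` and `V_B`: hold the exposure-model
#'   covariances fixed at these values instead of sampling them (used for
#'   validation against deterministic oracles).
#' @param include_disease Internal validation switch; `FALSE` mutes the
#'   disease likelihood so the conjugate exposure-model blocks can be checked
#'   in isolation.
#' @return A `chain_set`: per-chain posterior draws of `beta`, `delta`
#'   (and `V_W`, `V_B` when latent), the log-posterior trace, acceptance
#'   rates, and the final sampler state.
#' @export
run_mcmc <- function(study, spec = NULL, prior = default_prior(study),
                     config = sampler_config(), use_confounders = TRUE,
                     naive = is.null(spec), fix_cov = NULL,
                     include_disease = TRUE) {
  stopifnot(inherits(study, "matched_study"), inherits(config, "sampler_config"))
  inp <- study_inputs(study)
  if (!use_confounders) inp$Z <- inp$Z[, 0, drop = FALSE]
  P <- ncol(inp$W); K <- ncol(inp$Z)
  if (!naive) {
    stopifnot(inherits(spec, "me_spec"))
    if (length(spec$sigma2) != P) abort("spec$sigma2 length != number of exposures")
    if (any(spec$sigma2 <= 0)) {
      abort("zero error variance: fit the naive model instead (naive = TRUE)")
    }
  }
  if (length(prior$mu) != P) abort("prior$mu length != number of exposures")
  sigma2 <- if (naive) rep(1, P) else unname(spec$sigma2)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$base_seed + ch - 1L)
    ini <- mcmc_inits(inp, prior, chain = ch)
    if (!is.null(fix_cov)) {
      ini$VW <- fix_cov$V_W
      ini$VB <- fix_cov$V_B
    }
    if (!naive) {
      lp0 <- log_joint(list(beta = ini$beta, delta = ini$delta, X = ini$X,
                            M = ini$M, V_W = ini$VW, V_B = ini$VB),
                       study_from_inputs(study, inp), spec, prior)
      if (!is.finite(lp0)) {
        abort(paste0("non-finite log posterior at initial state of chain ", ch,
                     "; inits: beta=", paste(signif(ini$beta, 3), collapse = ","),
                     " VW[1,1]=", signif(ini$VW[1, 1], 3)))
      }
    }
    res <- cpp_run_chain(
      inp$W, inp$Z, inp$set_start, inp$set_size,
      sigma2, prior$mu, prior$beta_var, prior$delta_var,
      prior$wishart_R, prior$wishart_df,
      config$n_iter, config$n_burn, config$adapt_window,
      config$step_x, config$step_b, config$n_bd_updates,
      naive, !is.null(fix_cov), include_disease,
      ini$X, ini$M, ini$VW, ini$VB, ini$beta, ini$delta
    )
    colnames(res$beta) <- attr(study, "exposures")
    if (K > 0) colnames(res$delta) <- colnames(inp$Z)
    chains[[ch]] <- res
  }

  structure(list(chains = chains, config = config, naive = naive,
                 exposures = attr(study, "exposures"),
                 confounders = if (K > 0) colnames(inp$Z) else character(),
                 spec = if (naive) NULL else spec, prior = prior),
            class = "chain_set")
}

# rebuild a minimal matched_study view consistent with possibly-dropped Z
# (only used for the initial-state log_joint check)
study_from_inputs <- function(study, inp) {
  if (ncol(inp$Z) == length(attr(study, "confounders"))) return(study)
  attr(study, "confounders") <- colnames(inp$Z)
  study
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %d chain(s) x %d iterations (burn-in %d), %s model\n",
              x$config$n_chains, x$config$n_iter, x$config$n_burn,
              if (x$naive) "naive" else "measurement-error"))
  cat("  parameters:", paste(c(x$exposures, x$confounders), collapse = ", "), "\n")
  invisible(x)
}

# post-burn-in coefficient draws: list of matrices, one per chain, columns
# named by parameter (exposures then confounders)
coef_draws <- function(chains, warm = TRUE) {
  stopifnot(inherits(chains, "chain_set"))
  keep <- if (warm) (chains$config$n_burn + 1):chains$config$n_iter else
    seq_len(chains$config$n_iter)
  lapply(chains$chains, function(ch) {
    out <- ch$beta[keep, , drop = FALSE]
    if (length(chains$confounders) > 0) {
      out <- cbind(out, ch$delta[keep, , drop = FALSE])
    }
    out
  })
}

#' Gelman-Rubin convergence diagnostic (split-chain R-hat)
#'
#' Each post-burn-in chain is split in half and the potential scale reduction
#' factor `sqrt(((n-1)/n W + B/n) / W)` is computed across the split chains.
#' Values near 1 indicate the chains are consistent with a common stationary
#' distribution.
#'
#' @param chains A `chain_set` with at least 2 chains (or a list of equal
#'   length numeric vectors, one per chain).
#' @param params Optional character vector restricting to named parameters.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains, params = NULL) {
  draws <- if (inherits(chains, "chain_set")) {
    if (chains$config$n_chains < 2) abort("R-hat needs at least 2 chains")
    coef_draws(chains)
  } else {
    if (!is.list(chains) || length(chains) < 2) abort("R-hat needs at least 2 chains")
    lapply(chains, function(v) matrix(v, ncol = 1, dimnames = list(NULL, "param")))
  }
  nm <- colnames(draws[[1]])
  if (!is.null(params)) nm <- intersect(nm, params)
  vapply(nm, function(p) {
    halves <- unlist(lapply(draws, function(d) {
      v <- d[, p]
      n2 <- floor(length(v) / 2)
      list(v[seq_len(n2)], v[(length(v) - n2 + 1):length(v)])
    }), recursive = FALSE)
    n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, var, numeric(1))
    Wv <- mean(vars)
    Bn <- var(means)           # = B/n
    if (Wv == 0) return(if (Bn == 0) 1 else Inf)
    sqrt(((n - 1) / n * Wv + Bn) / Wv)
  }, numeric(1))
}

# batch-means MCSE of the mean of one vector of draws
batch_mcse <- function(v) {
  n <- length(v)
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(v[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  sqrt(b * var(bm) / (nb * b))
}

#' Monte Carlo standard error of posterior means (batch means)
#'
#' @param chains A `chain_set` (or a list of numeric vectors, one per chain).
#' @param params Optional character vector restricting to named parameters.
#' @return Named numeric vector: MCSE of the pooled posterior-mean estimate
#'   of each coefficient (log-OR scale).
#' @export
mcse <- function(chains, params = NULL) {
  draws <- if (inherits(chains, "chain_set")) coef_draws(chains) else
    lapply(chains, function(v) matrix(v, ncol = 1, dimnames = list(NULL, "param")))
  if (nrow(draws[[1]]) < 100) abort("need at least 100 post-burn-in draws")
  nm <- colnames(draws[[1]])
  if (!is.null(params)) nm <- intersect(nm, params)
  C <- length(draws)
  vapply(nm, function(p) {
    per_chain <- vapply(draws, function(d) batch_mcse(d[, p]), numeric(1))
    sqrt(sum(per_chain^2)) / C
  }, numeric(1))
}

#' Dump chains to CSV
#'
#' One row per retained iteration with `chain`, `iteration`, the coefficient
#' draws, and the log-posterior, for external diagnostics tooling.
#'
#' @param chains A `chain_set`.
#' @param path Output CSV path.
#' @param warm Drop burn-in iterations (default `TRUE`).
#' @return `path`, invisibly.
#' @export
dump_chains <- function(chains, path, warm = TRUE) {
  draws <- coef_draws(chains, warm = warm)
  keep <- if (warm) (chains$config$n_burn + 1):chains$config$n_iter else
    seq_len(chains$config$n_iter)
  tabs <- lapply(seq_along(draws), function(ch) {
    tibble::as_tibble(draws[[ch]]) |>
      dplyr::mutate(chain = ch, iteration = keep,
                    lp = chains$chains[[ch]]$lp[keep], .before = 1)
  })
  readr::write_csv(dplyr::bind_rows(tabs), path)
  invisible(path)
}
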