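#' Prior specification for the joint Bayesian model
#'
#' Diffuse proper priors: `beta_p ~ N(0, beta_var)` and
#' `delta_k ~ N(0, delta_var)` for the log odds ratios, and Wishart priors
#' `V_W^{-1}, V_B^{-1} ~ W_P(R, b)` on the within- and between-set precision
#' matrices of the exposure model (`R` the positive-definite inverse scale,
#' `b >= P` degrees of freedom). The exposure grand mean `mu` is a plug-in
#' constant, conventionally the across-set sample mean of the observed
#' surrogates (see [default_prior()]).
#'
#' @param mu Numeric vector of length `P`: plug-in exposure grand mean.
#' @param beta_var,delta_var Prior variances for each `beta_p` / `delta_k`
#'   (default `1e4`, reflecting prior ignorance).
#' @param wishart_R `P x P` positive-definite inverse scale (default
#'   `diag(P)`).
#' @param wishart_df Degrees of freedom `b >= P` (default `P`, the minimal
#'   proper choice).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu, beta_var = 1e4, delta_var = 1e4,
                       wishart_R = diag(length(mu)),
                       wishart_df = length(mu)) {
  P <- length(mu)
  stopifnot(beta_var > 0, delta_var > 0, wishart_df >= P,
            is.matrix(wishart_R), all(dim(wishart_R) == P))
  if (any(eigen(wishart_R, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("wishart_R must be positive definite")
  }
  structure(list(mu = mu, beta_var = beta_var, delta_var = delta_var,
                 wishart_R = wishart_R, wishart_df = wishart_df),
            class = "prior_spec")
}

#' Default prior for a study
#'
#' Builds a [prior_spec()] whose plug-in grand mean `mu` is the across-set
#' sample mean of the observed surrogate exposures (mean of the matched-set
#' means, so sets of different size weigh equally).
#'
#' @param study A `matched_study`.
#' @param ... Passed to [prior_spec()].
#' @export
default_prior <- function(study, ...) {
  inp <- study_inputs(study)
  grp <- rep(seq_along(inp$set_size), inp$set_size)
  set_means <- apply(inp$W, 2, function(col) tapply(col, grp, mean))
  prior_spec(mu = colMeans(as.matrix(set_means)), ...)
}

# multivariate normal log-density (covariance parameterization), via Cholesky
dmvnorm_log <- function(x, mean, cov) {
  L <- tryCatch(chol(cov), error = function(e) abort("covariance not positive definite"))
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Wishart log-density of S ~ W_P(R, b), R the INVERSE scale matrix
dwishart_log <- function(S, R, b) {
  P <- nrow(S)
  ldS <- determinant(S, logarithm = TRUE)$modulus
  ldR <- determinant(R, logarithm = TRUE)$modulus
  lmvgamma <- P * (P - 1) / 4 * log(pi) + sum(lgamma(b / 2 + (1 - seq_len(P)) / 2))
  as.numeric(0.5 * b * ldR + 0.5 * (b - P - 1) * ldS - 0.5 * sum(diag(R %*% S)) -
               0.5 * b * P * log(2) - lmvgamma)
}

#' Conditional logistic log-likelihood (disease model)
#'
#' The retrospective disease model for an individually matched design:
#' conditioning on one case per matched set, the contribution of set `i` is
#' `eta_i1 - log(sum_j exp(eta_ij))` with linear predictor
#' `eta_ij = X_ij' beta + Z_ij' delta` (the case is subject `j = 1`).
#' Stratum intercepts cancel, so the value is invariant to adding any
#' constant vector to every subject of a set. Computed with log-sum-exp
#' stabilisation.
#'
#' @param study A `matched_study` (provides the grouping and, by default, the
#'   observed exposures and confounders).
#' @param beta Numeric length-`P` log odds ratios per exposure unit.
#' @param delta Numeric length-`K` log odds ratios per confounder unit
#'   (omit or `numeric(0)` for the simple model).
#' @param X Optional `n x P` matrix of exposures at which to evaluate
#'   (defaults to the observed surrogates; pass latent values during
#'   measurement-error correction).
#' @return Scalar log conditional likelihood.
#' @export
log_disease <- function(study, beta, delta = numeric(0), X = NULL) {
  inp <- study_inputs(study)
  if (is.null(X)) X <- inp$W
  X <- as.matrix(X)
  if (!identical(dim(X), dim(inp$W))) abort("X has wrong dimensions")
  if (length(beta) != ncol(X)) abort("length(beta) != number of exposures")
  eta <- drop(X %*% beta)
  if (length(delta) > 0) {
    if (length(delta) != ncol(inp$Z)) abort("length(delta) != number of confounders")
    eta <- eta + drop(inp$Z %*% delta)
  }
  grp <- rep(seq_along(inp$set_size), inp$set_size)
  case_rows <- inp$set_start + 1L
  lse <- vapply(split(eta, grp), function(e) {
    m <- max(e); m + log(sum(exp(e - m)))
  }, numeric(1))
  sum(eta[case_rows]) - sum(lse)
}

#' Measurement-model log-density
#'
#' Classical additive error on the log scale: each surrogate coordinate is
#' `W_ijp ~ N(X_ijp, sigma2_p)` independently, so the log-density is the sum
#' of elementwise univariate normal log-densities.
#'
#' @param W,X `n x P` matrices of surrogate and true exposures.
#' @param spec An [me_spec()] with strictly positive variances.
#' @return Scalar log-density.
#' @export
log_measurement <- function(W, X, spec) {
  stopifnot(inherits(spec, "me_spec"))
  W <- as.matrix(W); X <- as.matrix(X)
  if (!identical(dim(W), dim(X))) abort("W and X must have identical shape")
  s2 <- spec$sigma2
  if (length(s2) != ncol(W)) abort("spec length != number of exposures")
  if (any(s2 == 0)) {
    abort("zero error variance: use the naive analysis (W == X) instead")
  }
  sum(vapply(seq_along(s2), function(p) {
    sum(dnorm(W[, p], X[, p], sqrt(s2[p]), log = TRUE))
  }, numeric(1)))
}

#' Random-effect exposure-model log-density
#'
#' Two-level multivariate normal model for the true exposures: set means
#' `M_i ~ N_P(mu, V_B)` (between-set) and subjects `X_ij ~ N_P(M_i, V_W)`
#' (within-set), with `V_W` constant across sets.
#'
#' @param study A `matched_study` (grouping only).
#' @param X `n x P` matrix of true exposures.
#' @param M `N x P` matrix of set-level exposure means.
#' @param prior A [prior_spec()] providing `mu`.
#' @param V_W,V_B `P x P` positive-definite within- and between-set
#'   covariance matrices.
#' @return Scalar log-density.
#' @export
log_exposure <- function(study, X, M, prior, V_W, V_B) {
  inp <- study_inputs(study)
  X <- as.matrix(X); M <- as.matrix(M)
  N <- length(inp$set_size)
  stopifnot(nrow(M) == N, ncol(M) == ncol(X), nrow(X) == nrow(inp$W))
  out <- 0
  for (i in seq_len(N)) {
    out <- out + dmvnorm_log(M[i, ], prior$mu, V_B)
    rows <- inp$set_start[i] + seq_len(inp$set_size[i])
    for (r in rows) out <- out + dmvnorm_log(X[r, ], M[i, ], V_W)
  }
  out
}

#' Log prior density
#'
#' Sum of the normal priors on `beta` and `delta` and the Wishart priors on
#' the two exposure-model precision matrices `V_W^{-1}` and `V_B^{-1}`.
#'
#' @param state List with elements `beta`, `delta`, `V_W`, `V_B` (a latent
#'   sampler state; `X`, `M` carry no prior mass beyond the exposure model).
#' @param prior A [prior_spec()].
#' @return Scalar log prior density.
#' @export
log_priors <- function(state, prior) {
  out <- sum(dnorm(state$beta, 0, sqrt(prior$beta_var), log = TRUE))
  if (length(state$delta) > 0) {
    out <- out + sum(dnorm(state$delta, 0, sqrt(prior$delta_var), log = TRUE))
  }
  if (!is.null(state$V_W)) {
    out <- out +
      dwishart_log(solve(state$V_W), prior$wishart_R, prior$wishart_df) +
      dwishart_log(solve(state$V_B), prior$wishart_R, prior$wishart_df)
  }
  out
}

#' Joint log-posterior density (up to the normalising constant)
#'
#' Sum of the measurement, disease (evaluated at the latent exposures),
#' exposure-model, and prior log-densities.
#'
#' @param state List with `beta`, `delta`, `X`, `M`, `V_W`, `V_B`.
#' @param study A `matched_study`.
#' @param spec An [me_spec()].
#' @param prior A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_joint <- function(state, study, spec, prior) {
  inp <- study_inputs(study)
  log_measurement(inp$W, state$X, spec) +
    log_disease(study, state$beta, state$delta, X = state$X) +
    log_exposure(study, state$X, state$M, prior, state$V_W, state$V_B) +
    log_priors(state, prior)
}
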