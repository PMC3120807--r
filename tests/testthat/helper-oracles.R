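# Independent oracles used across tests. Everything here is deliberately
# written from first principles (no calls into the package's own density or
# sampler code) so it can serve as a second route.

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix), for
# integrals of f against exp(-t^2)
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E[f(D)] for D ~ N(m, v) by Gauss-Hermite
gh_expect <- function(f, m, v, n = 64) {
  gh <- gauss_hermite(n)
  sum(gh$weights / sqrt(pi) * f(m + sqrt(2 * v) * gh$nodes))
}

# Deterministic oracle for the small-instance posterior of beta:
# P = 1 exposure, N sets of size 2, known error variance sigma2, fixed
# exposure-model variances (v_w within, v_b between), plug-in grand mean mu,
# prior beta ~ N(0, beta_var). Marginally X_i = (X_i1, X_i2) ~ N(mu 1, C)
# with C = v_b J + v_w I, and W_i | X_i ~ N(X_i, sigma2 I), so
# X_i | W_i ~ N(m_i, S). The conditional-logistic factor for set i is
# plogis(beta * (x_i1 - x_i2)) (case first), which depends on x only through
# the difference d = x_i1 - x_i2 ~ N(m_i1 - m_i2, S11 + S22 - 2 S12).
# The beta posterior is then a 1-D grid integral.
oracle_beta_posterior <- function(W2, mu, v_w, v_b, sigma2, beta_var,
                                  grid = seq(-8, 8, by = 0.005)) {
  stopifnot(ncol(W2) == 2)
  C <- matrix(v_b, 2, 2) + diag(v_w, 2)
  S <- solve(solve(C) + diag(2) / sigma2)
  m_d <- apply(W2, 1, function(w) {
    m <- S %*% (solve(C, rep(mu, 2)) + w / sigma2)
    m[1] - m[2]
  })
  v_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  log_post <- vapply(grid, function(b) {
    ll <- sum(vapply(m_d, function(md) {
      log(gh_expect(function(d) plogis(b * d), md, v_d))
    }, numeric(1)))
    ll + dnorm(b, 0, sqrt(beta_var), log = TRUE)
  }, numeric(1))
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  list(mean = sum(grid * w), sd = sqrt(sum(grid^2 * w) - sum(grid * w)^2))
}

# Newton-Raphson maximiser of the conditional-logistic log-likelihood
# Sum_i [eta_case - log sum_j exp(eta_ij)], coded directly from the design
# matrix (first row of each set is the case)
newton_clogit <- function(X, set_start, set_size, tol = 1e-10, maxit = 100) {
  p <- ncol(X)
  b <- rep(0, p)
  for (it in seq_len(maxit)) {
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (i in seq_along(set_start)) {
      rows <- set_start[i] + seq_len(set_size[i])
      Xi <- X[rows, , drop = FALSE]
      e <- drop(Xi %*% b)
      pr <- exp(e - max(e))
      pr <- pr / sum(pr)
      xbar <- drop(pr %*% Xi)
      g <- g + Xi[1, ] - xbar
      H <- H + t(Xi) %*% (pr * Xi) - outer(xbar, xbar)
    }
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# small synthetic studies for quick tests
tiny_study <- function(n_sets = 20, sizes = c("2" = 10, "3" = 10), seed = 42,
                       ...) {
  simulate_study(n_sets = n_sets, set_sizes = sizes, seed = seed, ...)
}

# fixed small single-exposure study with informative surrogates, shared by
# the quadrature-oracle tests
small_p1_study <- function(n_sets = 5, seed = 99) {
  simulate_study(
    n_sets = n_sets, set_sizes = setNames(n_sets, "2"),
    beta = log(2), delta = numeric(0), mu = 0,
    V_W = matrix(0.3), V_B = matrix(0.3), sigma2 = 0.05,
    exposures = "x", seed = seed
  )
}

# plain batch-means standard error for a single chain of draws
batch_se <- function(v) {
  b <- max(2L, floor(sqrt(length(v))))
  nb <- floor(length(v) / b)
  bm <- colMeans(matrix(v[seq_len(nb * b)], nrow = b))
  sqrt(stats::var(bm) / nb)
}


# exact SD of the simulated percent recovery when c = 0:
# Q = exp(sigma * (e_s - e_g)) is lognormal with log-variance 2 sigma^2
exact_recovery_sd_c0 <- function(sigma) {
  s2 <- 2 * sigma^2
  exp(s2 / 2) * sqrt(exp(s2) - 1)
}

# batch-quantile Monte Carlo standard error of an empirical quantile,
# pooled over chains (subsampling estimator; quantiles are asymptotically
# linear so the batch-means scaling applies)
quantile_mcse <- function(draws_list, p) {
  bq <- unlist(lapply(draws_list, function(v) {
    n <- length(v)
    b <- max(2L, floor(sqrt(n)))
    nb <- floor(n / b)
    vapply(seq_len(nb), function(i) {
      stats::quantile(v[((i - 1) * b + 1):(i * b)], p, names = FALSE)
    }, numeric(1))
  }))
  stats::sd(bq) / sqrt(length(bq))
}
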