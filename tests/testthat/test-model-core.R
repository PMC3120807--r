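make_pair_study <- function(x, z = NULL) {
  # one-exposure study from a matrix of per-set (case, control) values
  df <- data.frame(
    set = rep(seq_len(nrow(x)), each = 2),
    case = rep(c(1, 0), nrow(x)),
    w = as.vector(t(x))
  )
  if (!is.null(z)) df$z1 <- as.vector(t(z))
  matched_study(df, exposures = "w",
                confounders = if (is.null(z)) character() else "z1")
}

test_that("log_disease at beta = 0 equals -sum(log n_i) exactly", {
  st <- tiny_study(seed = 21)
  expect_identical(log_disease(st, beta = c(0, 0, 0), delta = rep(0, 4)),
                   -sum(log(set_sizes(st))))
  st2 <- simulate_study(seed = 22)
  expect_identical(log_disease(st2, beta = c(0, 0, 0)),
                   -sum(log(set_sizes(st2))))
})

test_that("log_disease matches brute-force enumeration on a single pair", {
  # one set, n=2, P=1, x = (1, 0), beta = 2: the case outcome has
  # probability e^2 / (e^2 + e^0)
  st <- make_pair_study(rbind(c(1, 0), c(0, 0)))
  got <- log_disease(st, beta = 2)
  want <- log(exp(2) / (exp(2) + 1)) + log(1 / 2)   # second set is x=(0,0)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(log(exp(2) / (exp(2) + 1)), -log(1 + exp(-2)))
})

test_that("per-set case-assignment probabilities exponentiate and sum to 1", {
  st <- tiny_study(seed = 23)
  inp <- matchedme:::study_inputs(st)
  beta <- c(0.3, -0.2, 0.5)
  delta <- c(0.02, -0.01, 0.3, 0.005)
  eta <- drop(inp$W %*% beta + inp$Z %*% delta)
  # exhaustively move the case label around each set; probabilities sum to 1
  for (i in seq_along(inp$set_size)) {
    rows <- inp$set_start[i] + seq_len(inp$set_size[i])
    pr <- exp(eta[rows]) / sum(exp(eta[rows]))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # and the set's contribution to log_disease is log pr[1]
  }
  # total log-likelihood equals the sum of per-set log case probabilities
  per_set <- vapply(seq_along(inp$set_size), function(i) {
    rows <- inp$set_start[i] + seq_len(inp$set_size[i])
    log(exp(eta[rows[1]]) / sum(exp(eta[rows])))
  }, numeric(1))
  expect_equal(log_disease(st, beta, delta), sum(per_set), tolerance = 1e-12)
})

test_that("log_disease is invariant to within-set constant shifts and control permutation", {
  st <- tiny_study(seed = 24)
  inp <- matchedme:::study_inputs(st)
  beta <- c(0.4, 0.1, -0.3)
  base <- log_disease(st, beta)
  # add a different constant vector to every member of each set
  X <- inp$W
  set.seed(1)
  for (i in seq_along(inp$set_size)) {
    rows <- inp$set_start[i] + seq_len(inp$set_size[i])
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, rnorm(3, sd = 5), `+`)
  }
  expect_equal(log_disease(st, beta, X = X), base, tolerance = 1e-9)
  # permute controls within sets (case stays first)
  df <- tibble::as_tibble(st)
  set.seed(2)
  df <- dplyr::group_by(df, set) |>
    dplyr::slice(c(1, 1 + sample(dplyr::n() - 1))) |>
    dplyr::ungroup()
  st2 <- matched_study(as.data.frame(df), exposures = attr(st, "exposures"),
                       confounders = attr(st, "confounders"))
  expect_equal(log_disease(st2, beta), base, tolerance = 1e-12)
})

test_that("log_measurement equals the sum of elementwise normal log-densities", {
  set.seed(31)
  W <- matrix(rnorm(12), 4, 3)
  X <- W + matrix(rnorm(12, sd = 0.3), 4, 3)
  s2 <- c(0.05, 0.1, 0.2)
  spec <- me_spec(s2)
  # independent oracle: elementwise dnorm
  want <- sum(vapply(1:3, function(p) {
    sum(dnorm(W[, p], X[, p], sqrt(s2[p]), log = TRUE))
  }, numeric(1)))
  expect_equal(log_measurement(W, X, spec), want, tolerance = 1e-12)
  # W == X: only the normalising constants remain
  expect_equal(log_measurement(W, W, spec),
               -4 / 2 * sum(log(2 * pi * s2)), tolerance = 1e-12)
  # single subject, P = 1, w - x = sigma
  expect_equal(log_measurement(matrix(sqrt(0.1)), matrix(0), me_spec(0.1)),
               -0.5 * log(2 * pi * 0.1) - 0.5, tolerance = 1e-12)
  expect_error(log_measurement(W, X, me_spec(c(0, 0.1, 0.1))), "naive")
})

test_that("log_exposure reduces to scalar normal densities when P = 1", {
  st <- make_pair_study(rbind(c(0.3, -0.2), c(1.1, 0.4), c(0, 0)))
  pr <- prior_spec(mu = 0.1)
  X <- matrix(c(0.3, -0.2, 1.1, 0.4, 0, 0))
  M <- matrix(c(0.1, 0.6, -0.2))
  vw <- 0.4; vb <- 0.7
  got <- log_exposure(st, X, M, pr, matrix(vw), matrix(vb))
  want <- sum(dnorm(M, 0.1, sqrt(vb), log = TRUE)) +
    sum(dnorm(X, M[rep(1:3, each = 2), ], sqrt(vw), log = TRUE))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("log_exposure at X = M = mu is the normalising constant", {
  st <- tiny_study(seed = 25)
  P <- 3
  mu <- c(-19, -18, -20)
  pr <- prior_spec(mu = mu)
  V_W <- diag(0.3, P) + 0.1
  V_B <- diag(0.5, P) + 0.05
  n <- nrow(st); N <- length(set_sizes(st))
  X <- matrix(mu, n, P, byrow = TRUE)
  M <- matrix(mu, N, P, byrow = TRUE)
  want <- -N / 2 * determinant(2 * pi * V_B)$modulus -
    n / 2 * determinant(2 * pi * V_W)$modulus
  expect_equal(log_exposure(st, X, M, pr, V_W, V_B), as.numeric(want),
               tolerance = 1e-10)
})

test_that("conditional exposure model integrates to the closed-form marginal over M", {
  # P = 1, one pair: integrating the set mean out of
  # N(M; mu, vb) * prod_j N(x_j; M, vw) gives x ~ N(mu 1, vb J + vw I).
  # Check by Gauss-Hermite integration over M against the bivariate density.
  mu <- 0.2; vw <- 0.35; vb <- 0.6
  x <- c(0.9, -0.3)
  lik_cond <- gh_expect(function(m) {
    vapply(m, function(mi) prod(dnorm(x, mi, sqrt(vw))), numeric(1))
  }, m = mu, v = vb, n = 80)
  C <- matrix(vb, 2, 2) + diag(vw, 2)
  want <- exp(-0.5 * drop(t(x - mu) %*% solve(C, x - mu))) /
    (2 * pi * sqrt(det(C)))
  expect_equal(lik_cond, want, tolerance = 1e-8)
  # and the package's conditional form evaluates the same integrand
  st <- make_pair_study(rbind(x, c(0, 0)))
  pr <- prior_spec(mu = mu)
  at_m <- function(m) {
    exp(log_exposure(st, matrix(c(x, 0, 0)), matrix(c(m, 0)), pr,
                     matrix(vw), matrix(vb)))
  }
  direct <- dnorm(0, mu, sqrt(vb)) * prod(dnorm(c(0, 0), 0, sqrt(vw)))
  expect_equal(at_m(0.4),
               dnorm(0.4, mu, sqrt(vb)) * prod(dnorm(x, 0.4, sqrt(vw))) * direct,
               tolerance = 1e-12)
})

test_that("wishart log-density matches the gamma reduction when P = 1", {
  # W_1(R, b) with inverse scale R is Gamma(shape b/2, rate R/2)
  for (s in c(0.3, 1, 2.7)) {
    for (b in c(1, 3, 7)) {
      for (r in c(0.5, 2)) {
        got <- matchedme:::dwishart_log(matrix(s), matrix(r), b)
        want <- stats::dgamma(s, shape = b / 2, rate = r / 2, log = TRUE)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("log_priors: normal terms and beta_var scaling behave", {
  pr <- prior_spec(mu = c(0, 0), beta_var = 1e4, delta_var = 1e4)
  st0 <- list(beta = c(0, 0), delta = numeric(0),
              V_W = diag(2), V_B = diag(2))
  # at beta = 0 the normal part contributes only normalising constants
  got <- log_priors(st0, pr)
  wish <- 2 * matchedme:::dwishart_log(diag(2), diag(2), 2)
  expect_equal(got - wish, 2 * dnorm(0, 0, 100, log = TRUE), tolerance = 1e-12)
  # doubling beta_var lowers the zero log-density by log(2)/2 per coordinate
  pr2 <- prior_spec(mu = c(0, 0), beta_var = 2e4)
  expect_equal(log_priors(st0, pr) - log_priors(st0, pr2),
               2 * 0.5 * log(2), tolerance = 1e-12)
})

test_that("log_joint is the sum of its four components and behaves in X", {
  st <- tiny_study(seed = 26)
  inp <- matchedme:::study_inputs(st)
  pr <- default_prior(st)
  spec <- me_spec(c(0.05, 0.08, 0.1))
  set.seed(4)
  N <- length(set_sizes(st))
  state <- list(beta = rnorm(3, sd = 0.2), delta = rnorm(4, sd = 0.1),
                X = inp$W + matrix(rnorm(length(inp$W), sd = 0.1),
                                   nrow(inp$W)),
                M = matrix(rnorm(N * 3, mean = rep(pr$mu, each = N), sd = 0.3),
                           N, 3),
                V_W = diag(0.4, 3), V_B = diag(0.6, 3))
  total <- log_joint(state, st, spec, pr)
  parts <- log_measurement(inp$W, state$X, spec) +
    log_disease(st, state$beta, state$delta, X = state$X) +
    log_exposure(st, state$X, state$M, pr, state$V_W, state$V_B) +
    log_priors(state, pr)
  expect_equal(total, parts, tolerance = 1e-10)
  expect_true(is.finite(total))

  # moving one coordinate away from both its surrogate and its set mean can
  # only lower the joint density when beta = 0
  state0 <- state
  state0$beta <- rep(0, 3)
  base <- log_joint(state0, st, spec, pr)
  state1 <- state0
  grp <- rep(seq_len(N), set_sizes(st))
  dir <- sign(state0$X[1, 1] - state0$M[grp[1], 1])
  if (dir == 0) dir <- 1
  # push past both anchors
  state1$X[1, 1] <- max(inp$W[1, 1], state0$M[grp[1], 1]) + 2
  state2 <- state1
  state2$X[1, 1] <- state1$X[1, 1] + 1
  expect_lt(log_joint(state1, st, spec, pr), base)
  expect_lt(log_joint(state2, st, spec, pr), log_joint(state1, st, spec, pr))
})

test_that("as error variance grows the joint X-dependence collapses to disease+exposure", {
  st <- tiny_study(seed = 27)
  inp <- matchedme:::study_inputs(st)
  pr <- default_prior(st)
  big <- me_spec(rep(1e8, 3))
  set.seed(5)
  N <- length(set_sizes(st))
  common <- list(beta = c(0.2, -0.1, 0.3), delta = rep(0, 4),
                 M = matrix(rep(pr$mu, each = N), N, 3),
                 V_W = diag(0.4, 3), V_B = diag(0.6, 3))
  X1 <- inp$W + 0.3
  X2 <- inp$W - 0.5
  s1 <- c(common, list(X = X1)); s2 <- c(common, list(X = X2))
  dj <- log_joint(s1, st, big, pr) - log_joint(s2, st, big, pr)
  dde <- (log_disease(st, s1$beta, s1$delta, X = X1) +
            log_exposure(st, X1, common$M, pr, common$V_W, common$V_B)) -
    (log_disease(st, s2$beta, s2$delta, X = X2) +
       log_exposure(st, X2, common$M, pr, common$V_W, common$V_B))
  expect_equal(dj, dde, tolerance = 1e-4)
})

test_that("log densities stay finite on random valid states", {
  st <- tiny_study(seed = 28)
  inp <- matchedme:::study_inputs(st)
  pr <- default_prior(st)
  spec <- me_spec(c(0.1, 0.1, 0.1))
  N <- length(set_sizes(st))
  set.seed(6)
  for (rep in 1:20) {
    A <- matrix(rnorm(9), 3)
    state <- list(beta = rnorm(3, sd = 2), delta = rnorm(4, sd = 2),
                  X = inp$W + matrix(rnorm(length(inp$W)), nrow(inp$W)),
                  M = matrix(rnorm(N * 3), N, 3),
                  V_W = crossprod(A) + diag(0.01, 3),
                  V_B = crossprod(matrix(rnorm(9), 3)) + diag(0.01, 3))
    expect_true(is.finite(log_joint(state, st, spec, pr)))
  }
})
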