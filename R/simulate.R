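#' Simulate an individually matched case-control study
#'
#' Generates data with exactly the statistical structure the joint model
#' assumes, emulating the shape of a serum-biomarker matched study: `N`
#' matched sets of size 2-4, `P` continuous exposures with two-level
#' multivariate-normal structure, and `K` precisely measured confounders.
#' For each set `i` the set mean is drawn as `M_i ~ N_P(mu, V_B)`, each
#' member's true exposure as `X_ij ~ N_P(M_i, V_W)`, and the single case is
#' assigned within the set with probability proportional to
#' `exp(X_ij' beta + Z_ij' delta)` — the exact law the conditional logistic
#' likelihood describes, so no sets are discarded. Surrogates are
#' `W_ij = X_ij + U_ij` with `U_ijp ~ N(0, sigma2_p)` drawn independently of
#' case status (non-differential error by construction).
#'
#' The default confounder scheme (for `K = 4`) mimics maternal age (also a
#' matching factor: large between-set, small within-set spread), maternal
#' weight, a binary race indicator, and gestational age. Continuous
#' confounders load weakly on the set-level exposure deviations so that
#' exposure-confounder correlations stay below 0.18 in absolute value; for
#' other `K`, standard-normal confounders (the last one binary when
#' `K >= 2`) with the same weak loading are used.
#'
#' @param n_sets Number of matched sets `N` (default 96).
#' @param set_sizes Named counts of sets per size, e.g.
#'   `c("2" = 21, "3" = 71, "4" = 4)` (the default, 271 subjects in all);
#'   must sum to `n_sets`.
#' @param beta True log ORs per exposure (length `P`); default
#'   `log(c(0.9, 0.8, 1.3))`, a realistic weak-effect regime.
#' @param delta True log ORs per confounder (length `K`, may be
#'   `numeric(0)`); default `rep(0, 4)`.
#' @param mu Grand mean of the exposures on the log-molar scale.
#' @param V_B,V_W Between- and within-set exposure covariance matrices
#'   (default: variance 0.35 each with pairwise correlation 0.3).
#' @param sigma2 Per-exposure measurement-error variances (default such that
#'   the error SD is 30% of the total exposure SD, a moderate-error regime).
#' @param exposures,confounders Column names.
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return A `matched_study` tibble (case first per set) with the generating
#'   truth in `attr(x, "truth")`: `beta`, `delta`, `X`, `M`, `mu`, `V_W`,
#'   `V_B`, `sigma2`, `seed`.
#' @export
simulate_study <- function(n_sets = 96,
                           set_sizes = c("2" = 21, "3" = 71, "4" = 4),
                           beta = log(c(0.9, 0.8, 1.3)),
                           delta = rep(0, 4),
                           mu = c(-19.2, -17.7, -19.8),
                           V_B = NULL, V_W = NULL, sigma2 = NULL,
                           exposures = NULL, confounders = NULL,
                           seed = NULL) {
  P <- length(beta)
  K <- length(delta)
  if (length(mu) != P) {
    mu <- if (P <= 3) mu[seq_len(P)] else c(mu, rep(mean(mu), P - 3))
  }
  corr <- 0.3 * (1 - diag(P)) + diag(P)
  if (is.null(V_B)) V_B <- 0.35 * corr
  if (is.null(V_W)) V_W <- 0.35 * corr
  if (is.null(sigma2)) sigma2 <- 0.09 * (diag(V_W) + diag(V_B))
  stopifnot(length(sigma2) == P, all(sigma2 >= 0),
            all(dim(V_B) == P), all(dim(V_W) == P))
  if (is.null(exposures)) {
    exposures <- if (P == 3) c("pfoa", "pfos", "pfhxs") else paste0("exp", seq_len(P))
  }
  if (is.null(confounders) && K > 0) {
    confounders <- if (K == 4) c("age", "weight", "race", "gest_age") else
      paste0("z", seq_len(K))
  }
  sizes <- rep(as.integer(names(set_sizes)), times = set_sizes)
  if (length(sizes) != n_sets) abort("set_sizes counts must sum to n_sets")
  if (any(sizes < 2)) abort("every matched set needs at least 2 members")
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(sizes)   # shuffle set sizes across set labels
  n <- sum(sizes)
  grp <- rep(seq_len(n_sets), sizes)

  LB <- t(chol(V_B))
  LW <- t(chol(V_W))
  M <- t(mu + LB %*% matrix(rnorm(n_sets * P), P))
  X <- M[grp, , drop = FALSE] + t(LW %*% matrix(rnorm(n * P), P))

  # set-level standardized exposure deviation driving weak confounder links
  d_set <- rowMeans(sweep(M, 2, mu) %*% diag(1 / sqrt(diag(V_B)), P))
  Z <- matrix(0, n, K)
  if (K > 0) {
    scheme <- if (K == 4) {
      list(means = c(30, 150, NA, 115), sds = c(4.5, 25, NA, 10),
           load = c(0.25, 0.25, NA, 0.20), binary = c(FALSE, FALSE, TRUE, FALSE))
    } else {
      list(means = rep(0, K), sds = rep(1, K), load = rep(0.2, K),
           binary = c(rep(FALSE, max(0, K - 1)), K >= 2))
    }
    for (k in seq_len(K)) {
      if (scheme$binary[k]) {
        p_i <- plogis(qlogis(0.3) + 0.5 * d_set)
        Z[, k] <- rbinom(n, 1, p_i[grp])
      } else if (K == 4 && k == 1) {
        # age: matching factor — common set level, small within-set spread
        z_set <- scheme$means[k] +
          scheme$sds[k] * (scheme$load[k] * d_set +
                             sqrt(1 - scheme$load[k]^2) * rnorm(n_sets))
        Z[, k] <- z_set[grp] + runif(n, -2, 2)
      } else {
        Z[, k] <- scheme$means[k] +
          scheme$sds[k] * (scheme$load[k] * d_set[grp] +
                             sqrt(1 - scheme$load[k]^2) * rnorm(n))
      }
    }
    colnames(Z) <- confounders
  }

  # conditional one-case-per-set assignment: P(case = j) prop exp(eta_ij)
  eta <- drop(X %*% beta) + if (K > 0) drop(Z %*% delta) else 0
  case <- integer(n)
  for (i in seq_len(n_sets)) {
    rows <- which(grp == i)
    e <- eta[rows]
    pr <- exp(e - max(e))
    case[rows[sample.int(length(rows), 1, prob = pr)]] <- 1L
  }

  U <- t(sqrt(sigma2) * matrix(rnorm(n * P), P))
  W <- X + U
  colnames(W) <- exposures

  # case-first within set, so truth rows stay aligned with the study rows
  ord <- order(grp, -case)
  W <- W[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  if (K > 0) Z <- Z[ord, , drop = FALSE]
  case <- case[ord]
  grp <- grp[ord]

  df <- tibble::as_tibble(W)
  if (K > 0) df <- dplyr::bind_cols(df, tibble::as_tibble(Z))
  df <- dplyr::mutate(df,
                      set = sprintf("set%03d", grp),
                      case = case, .before = 1)
  study <- matched_study(df, exposures = exposures,
                         confounders = if (K > 0) confounders else character())
  attr(study, "truth") <- list(beta = setNames(beta, exposures),
                               delta = if (K > 0) setNames(delta, confounders) else delta,
                               X = X, M = M, mu = mu, V_W = V_W, V_B = V_B,
                               sigma2 = setNames(sigma2, exposures),
                               seed = seed)
  class(study) <- c("synthetic_study", class(study))
  study
}

#' Censor a simulated study at a limit of detection
#'
#' Back-transforms the observed log-molar surrogates to the concentration
#' scale (`concentration = m_p * exp(W)`), flags every value below the
#' per-exposure limit of detection as a non-detect, and returns the result as
#' a [raw_concentration_table()] ready for [apply_lod()] /
#' [to_log_molar()]. The realised censoring fraction is reported.
#'
#' @param study A study from [simulate_study()].
#' @param lod Named numeric vector: limit of detection per exposure, on the
#'   concentration scale.
#' @param m Named numeric vector of conversion factors (concentration units
#'   per molar unit); defaults to units in which each exposure's
#'   geometric-mean concentration is 1.
#' @return A list: `table` (a `raw_concentrations` tibble with `NA` marking
#'   non-detects), `fraction` (realised non-detect fraction per exposure) and
#'   `fraction_overall`.
#' @export
censor_study <- function(study, lod, m = NULL) {
  stopifnot(inherits(study, "matched_study"))
  expos <- attr(study, "exposures")
  W <- as.matrix(study[expos])
  if (is.null(m)) m <- setNames(exp(-colMeans(W)), expos)
  if (!all(expos %in% names(m)) || !all(expos %in% names(lod))) {
    abort("`lod` and `m` must be named per exposure")
  }
  conc <- sweep(exp(W), 2, m[expos], `*`)
  nd <- sweep(conc, 2, lod[expos], `<`)
  conc[nd] <- NA_real_
  tab <- raw_concentration_table(tibble::as_tibble(conc), lod = lod, m = m)
  list(table = tab,
       fraction = colMeans(nd),
       fraction_overall = mean(nd))
}
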