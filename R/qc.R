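#' Measurement-error specification
#'
#' The classical additive error model on the log scale assumes surrogate
#' `W = X + U` with `U ~ N_P(0, Sigma)` and `Sigma = diag(sigma2)` known.
#'
#' @param sigma2 Named (or unnamed) numeric vector of per-exposure error
#'   variances on the log scale; all `>= 0`.
#' @param scale_factor Multiplier already applied to `sigma2` (bookkeeping for
#'   sensitivity sweeps); default 1.
#' @return An object of class `me_spec`.
#' @export
me_spec <- function(sigma2, scale_factor = 1) {
  if (any(sigma2 < 0)) abort("error variances must be non-negative")
  structure(list(sigma2 = sigma2, scale_factor = scale_factor),
            class = "me_spec")
}

#' @export
print.me_spec <- function(x, ...) {
  cat("<me_spec> sigma^2 =", paste(signif(x$sigma2, 4), collapse = ", "),
      sprintf(" (scale factor %g)\n", x$scale_factor))
  invisible(x)
}

#' Scale a measurement-error specification
#'
#' Multiplies every per-exposure error variance by `factor`, as used by the
#' sensitivity analysis over assumed error magnitude.
#'
#' @param spec An `me_spec`.
#' @param factor Non-negative scalar.
#' @return A new `me_spec` with `sigma2 * factor` and the cumulative
#'   `scale_factor` recorded.
#' @export
scale_sigma2 <- function(spec, factor) {
  stopifnot(inherits(spec, "me_spec"))
  if (length(factor) != 1 || factor < 0) abort("`factor` must be a scalar >= 0")
  me_spec(spec$sigma2 * factor, scale_factor = spec$scale_factor * factor)
}

# delta-method variance inflation factor for the percent recovery:
# Var(Q) ~= sigma^2 * g(c, a), gradient of Q taken at eps = 0
recovery_g <- function(c, spike) {
  (c / spike)^2 + ((c + spike) / spike)^2 + 1
}

#' Estimate error variances from percent-recovery QC data
#'
#' In the quality-control experiment, a pooled serum sample is measured
#' unspiked and spiked (spike amount `a`, e.g. 50 ppb), along with a gold
#' standard of the spike alone; the percent recovery is
#' `Q = (spiked - unspiked) / gold`. Under the lognormal (classical on the
#' log scale) error model with per-exposure log-scale variance `sigma^2`, a
#' first-order multivariate delta expansion of `Q` around zero error gives
#' `Var(Q) ~= sigma^2 * g(c, a)` with
#' `g(c, a) = (c/a)^2 + ((c+a)/a)^2 + 1`,
#' where `c` is the (mean) true sample concentration. Inverting yields the
#' error-variance estimate `sigma^2 = sd_recovery^2 / g(c, a)`.
#'
#' @param qc Data frame with one row per exposure and columns `name`,
#'   `sd_recovery` (SD of percent recoveries, on the fraction scale, e.g.
#'   0.157 not 15.7), `mean_concentration` (mean sample concentration `c`,
#'   same units as the spike; typically the across-sample average of the
#'   recorded concentrations), `spike` (spike amount `a > 0`).
#' @return An `me_spec` with named `sigma2`.
#' @seealso [simulate_recovery()] for the Monte-Carlo check of the
#'   approximation.
#' @export
#' @examples
#' qc <- data.frame(name = "pfoa", sd_recovery = 0.157,
#'                  mean_concentration = 10, spike = 50)
#' estimate_sigma2(qc)
estimate_sigma2 <- function(qc) {
  qc <- tibble::as_tibble(qc)
  need <- c("name", "sd_recovery", "mean_concentration", "spike")
  if (!all(need %in% names(qc))) {
    abort(paste0("qc table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(qc$spike <= 0)) abort("spike amount must be > 0")
  if (any(qc$sd_recovery < 0) || any(qc$mean_concentration < 0)) {
    abort("sd_recovery and mean_concentration must be non-negative")
  }
  g <- recovery_g(qc$mean_concentration, qc$spike)
  me_spec(setNames(qc$sd_recovery^2 / g, qc$name))
}

#' Read a percent-recovery QC table from CSV
#'
#' @param path CSV with columns `name`, `sd_recovery`, `mean_concentration`,
#'   `spike` (one row per exposure).
#' @return A tibble suitable for [estimate_sigma2()].
#' @export
read_qc <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Simulate the percent-recovery experiment
#'
#' Monte-Carlo oracle for the delta-method approximation in
#' [estimate_sigma2()]: draws independent standard-normal errors for the
#' unspiked, spiked, and gold-standard measurements,
#' `Q = ((c + a) exp(s e_s) - c exp(s e)) / (a exp(s e_g))`,
#' and returns the sample SD of `Q`.
#'
#' @param sigma Log-scale error SD (`>= 0`).
#' @param c True unspiked concentration.
#' @param spike Spike amount `a > 0`.
#' @param n_reps Number of replicates (`>= 2`).
#' @param seed Optional integer seed.
#' @return Sample standard deviation of the simulated recoveries.
#' @export
simulate_recovery <- function(sigma, c, spike, n_reps = 1e5, seed = NULL) {
  stopifnot(sigma >= 0, spike > 0, n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n_reps); es <- rnorm(n_reps); eg <- rnorm(n_reps)
  q <- ((c + spike) * exp(sigma * es) - c * exp(sigma * e)) /
    (spike * exp(sigma * eg))
  sd(q)
}
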