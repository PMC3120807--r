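#' Plot posterior odds-ratio distributions
#'
#' Kernel density of the pooled posterior OR draws per coefficient, with the
#' posterior mean and equal-tailed 95% credible interval marked and the null
#' (OR = 1) as a reference line.
#'
#' @param object An `me_fit`.
#' @param terms Optional subset of coefficient names (defaults to the
#'   exposure terms).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.me_fit <- function(object, terms = NULL, ...) {
  cs <- object$chains
  pooled <- do.call(rbind, coef_draws(cs))
  if (is.null(terms)) terms <- cs$exposures
  dat <- tidyr::pivot_longer(
    tibble::as_tibble(exp(pooled[, terms, drop = FALSE])),
    cols = dplyr::everything(), names_to = "term", values_to = "or"
  )
  marks <- dplyr::filter(object$summary, .data$term %in% terms)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$estimate)) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$conf.low),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$conf.high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "odds ratio", y = "posterior density")
}

#' Plot a sensitivity sweep
#'
#' Posterior mean ORs with 95% credible intervals against the error-variance
#' scale factor, one panel per coefficient.
#'
#' @param object A `sensitivity_result` from [sensitivity_sweep()].
#' @param terms Optional subset of coefficient names.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_result <- function(object, terms = NULL, ...) {
  dat <- object
  if (!is.null(terms)) dat <- dplyr::filter(dat, .data$term %in% terms)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scale_factor,
                                    y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "error-variance scale factor",
                  y = "posterior mean OR (95% CrI)")
}

#' Trace plot of coefficient draws
#'
#' @param fit An `me_fit` or `chain_set`.
#' @param terms Optional subset of coefficient names.
#' @param warm Drop burn-in iterations (default `TRUE`).
#' @return A ggplot object with one panel per coefficient, coloured by chain.
#' @export
plot_trace <- function(fit, terms = NULL, warm = TRUE) {
  cs <- if (inherits(fit, "me_fit")) fit$chains else fit
  stopifnot(inherits(cs, "chain_set"))
  draws <- coef_draws(cs, warm = warm)
  keep <- if (warm) (cs$config$n_burn + 1):cs$config$n_iter else
    seq_len(cs$config$n_iter)
  dat <- dplyr::bind_rows(lapply(seq_along(draws), function(ch) {
    tibble::as_tibble(draws[[ch]]) |>
      dplyr::mutate(chain = factor(ch), iteration = keep) |>
      tidyr::pivot_longer(cols = -c("chain", "iteration"),
                          names_to = "term", values_to = "value")
  }))
  if (!is.null(terms)) dat <- dplyr::filter(dat, .data$term %in% terms)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value,
                                    colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(y = "log OR draw")
}
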