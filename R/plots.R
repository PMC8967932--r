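#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of the fixed effects
#'
#' Point estimates with 95% Wald intervals
#' (`estimate +/- 1.96 * std.error`), one row per covariate.
#'
#' @param object a `dlmm_fit`.
#' @param estimator covariance estimator, `"model"` or `"sandwich"`.
#' @param intercept include the intercept row (default `FALSE`; it usually
#'   dominates the scale).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dlmm_fit
#' @export
autoplot.dlmm_fit <- function(object, estimator = c("model", "sandwich"),
                              intercept = FALSE, ...) {
  estimator <- match.arg(estimator)
  d <- tidy.dlmm_fit(object, estimator = estimator)
  if (!intercept) d <- d[d$term != "(Intercept)", , drop = FALSE]
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL,
                  title = "Fixed effects",
                  subtitle = paste0(estimator, " standard errors")) +
    ggplot2::theme_minimal()
}

#' Caterpillar plot of per-site random-effect predictions
#'
#' Site-specific effects (fixed effect + BLUP) with 95% prediction
#' intervals, faceted by random-effect term. The dashed line marks the
#' common fixed effect.
#'
#' @param object a `dlmm_blup`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dlmm_blup
#' @export
autoplot.dlmm_blup <- function(object, ...) {
  d <- tidy.dlmm_blup(object)
  fixed <- tibble::tibble(term = names(object$fixed),
                          fixed = unname(object$fixed))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site_effect, y = .data$site)) +
    ggplot2::geom_vline(data = fixed,
                        ggplot2::aes(xintercept = .data$fixed),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$pi.low, xmax = .data$pi.high),
      height = 0.2) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "site-specific effect (95% prediction interval)",
                  y = NULL, title = "Per-site effects") +
    ggplot2::theme_minimal()
}

#' Selection-trace plot
#'
#' Mixture p-values of every forward-selection test by step; accepted
#' candidates are filled.
#'
#' @param object a `dlmm_selection`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dlmm_selection
#' @export
autoplot.dlmm_selection <- function(object, ...) {
  d <- object$trace
  if (!nrow(d)) {
    stop("empty selection trace: no candidates were tested", call. = FALSE)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$step),
                                  y = .data$p.value,
                                  shape = .data$accepted)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(size = 2.5,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selection step", y = "mixture p-value (log scale)",
                  title = "Forward selection of random effects") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
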