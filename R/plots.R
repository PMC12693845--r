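# ggplot2 displays for fitted objects and reports.

#' Forest plot of risk ratios
#'
#' @param object An `rr_fit`.
#' @param intercept Include the intercept row (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rr_fit <- function(object, intercept = FALSE, ...) {
  d <- tidy(object)
  if (!intercept) d <- d[d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Risk ratio (95% CI, robust)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot attributable fractions with confidence intervals
#'
#' @param object A `paf_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paf_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Population attributable fraction (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pipeline report's risk ratios
#'
#' @param object A `meddiet_report`.
#' @param ... Unused.
#' @return A ggplot faceted by model (crude/adjusted).
#' @export
autoplot.meddiet_report <- function(object, ...) {
  d <- object$rr_table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rr, y = toupper(.data$score))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Risk ratio, low vs high adherence (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
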