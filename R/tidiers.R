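# broom-style tidiers for fitted objects.

#' Tidy a modified Poisson fit
#'
#' @param x An `rr_fit`.
#' @param exponentiate Report risk ratios (`TRUE`, default) or log risk
#'   ratios.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` (robust, log
#'   scale), `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.rr_fit <- function(x, exponentiate = TRUE, ...) {
  t <- x$terms
  if (exponentiate) {
    tibble::tibble(term = t$term, estimate = t$rr, std.error = t$robust_se,
                   statistic = t$estimate / t$robust_se, p.value = t$p_value,
                   conf.low = t$conf_low, conf.high = t$conf_high)
  } else {
    tibble::tibble(term = t$term, estimate = t$estimate,
                   std.error = t$robust_se,
                   statistic = t$estimate / t$robust_se, p.value = t$p_value,
                   conf.low = log(t$conf_low), conf.high = log(t$conf_high))
  }
}

#' Glance at a modified Poisson fit
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `deviance`, `converged`, `iterations`,
#'   `df` (number of coefficients).
#' @export
glance.rr_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_used, deviance = x$deviance,
                 converged = x$converged, iterations = x$iterations,
                 df = length(x$coefficients))
}

#' Tidy an attributable-fraction result
#'
#' @param x A `paf_result`.
#' @param ... Unused.
#' @return The underlying tibble with broom-style column names.
#' @export
tidy.paf_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::rename(estimate = "paf", conf.low = "conf_low",
                  conf.high = "conf_high")
}

#' Tidy an attrition log
#'
#' @param x An `attrition_log`.
#' @param ... Unused.
#' @return The attrition steps as a plain tibble.
#' @export
tidy.attrition_log <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
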