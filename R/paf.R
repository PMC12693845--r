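# Population attributable fractions from fitted risk-ratio models, with
# delta-method or bootstrap confidence intervals.
#
# The point estimate follows the case-based attributable-fraction identity
#   PAF% = 100 * Pe * (RR - 1) / RR,
# with Pe the proportion of cases that are exposed. An alternative reading
# of Pe as the population exposure prevalence (Levin's formula) is provided
# for sensitivity analysis via `form = "levin"`.

#' Attributable-fraction point estimate
#'
#' @param pe For `form = "case"` (default), the proportion of cases that
#'   are exposed; for `form = "levin"`, the exposure prevalence in the
#'   whole population. Must lie in \[0, 1\].
#' @param rr Risk ratio for the exposure (> 0).
#' @param form `"case"` (Miettinen, case-based) or `"levin"`.
#' @return PAF in percent. Zero when `rr = 1`; negative for protective
#'   exposures (never truncated).
#' @examples
#' paf_point(847 / 2071, 1.41096)  # 11.91
#' paf_point(1, 2)                 # 50
#' @export
paf_point <- function(pe, rr, form = c("case", "levin")) {
  form <- match.arg(form)
  if (any(pe < 0 | pe > 1, na.rm = TRUE)) abort("pe must lie in [0, 1]")
  if (any(rr <= 0, na.rm = TRUE)) abort("rr must be positive")
  switch(form,
    case  = 100 * pe * (rr - 1) / rr,
    levin = 100 * pe * (rr - 1) / (1 + pe * (rr - 1))
  )
}

paf_of_beta <- function(beta, pe) 100 * pe * (1 - exp(-beta))

paf_grad_analytic <- function(beta, pe) 100 * pe * exp(-beta)

paf_grad_fd <- function(beta, pe, rel_step = 1e-6) {
  h <- rel_step * max(1, abs(beta))
  (paf_of_beta(beta + h, pe) - paf_of_beta(beta - h, pe)) / (2 * h)
}

exposure_info <- function(fit, data, exposure) {
  terms <- fit$exposure_terms[[exposure]]
  if (is.null(terms)) {
    abort(paste0("Exposure '", exposure, "' not present in fit"))
  }
  if (length(terms) != 1) {
    abort("Attributable fractions are defined here for dichotomous exposures")
  }
  cols <- c(fit$outcome, fit$exposures, fit$covariates)
  use <- stats::complete.cases(data[cols])
  df <- data[use, , drop = FALSE]
  y <- as.numeric(df[[fit$outcome]])
  exposed_level <- setdiff(fit$exposure_levels[[exposure]],
                           fit$exposure_levels[[exposure]][1])
  exposed <- df[[exposure]] == exposed_level
  cases <- sum(y == 1)
  cases_exposed <- sum(y == 1 & exposed)
  if (cases_exposed == 0) {
    abort(paste0("No exposed cases for '", exposure, "': Pe undefined"))
  }
  list(term = terms, pe = cases_exposed / cases, cases = cases,
       exposed_level = exposed_level, exposed_num = as.numeric(exposed))
}

#' Delta-method confidence interval for the attributable fraction
#'
#' Treats the PAF as a smooth function
#' `g(beta, Pe) = 100 * Pe * (1 - exp(-beta))` of the fitted log risk ratio
#' and the proportion of cases exposed, and propagates sampling variability
#' by a first-order Taylor expansion on the PAF scale directly. By default
#' both sources of uncertainty enter through their per-participant
#' influence functions -- the robust (sandwich) influence of the
#' coefficient and the case-sampling influence of Pe -- so the interval
#' accounts for their correlation; `pe_variance = FALSE` conditions on the
#' observed Pe and uses the coefficient variance alone,
#' `CI = g +/- 1.959964 * sqrt(g'(beta)^2 * Var_robust(beta))`. The
#' analytic gradient in `beta` is cross-checked against a central finite
#' difference (relative step 1e-6).
#'
#' @param fit An `rr_fit` from [fit_modified_poisson()].
#' @param data The data the model was fitted to (used for Pe).
#' @param exposure Which exposure column to evaluate; default all exposures
#'   in the fit (joint models yield one row each from the single fit).
#' @param pe_variance Include the sampling variability of Pe (default
#'   `TRUE`).
#' @return A tibble of class `paf_result`: `exposure`, `pe`, `rr`,
#'   `excess_cases`, `paf`, `conf_low`, `conf_high`, `method = "delta"`.
#' @export
paf_delta_ci <- function(fit, data, exposure = fit$exposures,
                         pe_variance = TRUE) {
  if (!fit$converged) abort("paf_delta_ci(): model fit did not converge")
  rows <- purrr::map(exposure, function(ex) {
    info <- exposure_info(fit, data, ex)
    beta <- fit$coefficients[[info$term]]
    g <- paf_of_beta(beta, info$pe)
    grad_b <- paf_grad_analytic(beta, info$pe)
    grad_f <- paf_grad_fd(beta, info$pe)
    if (abs(grad_b) > 1e-10 && abs(grad_f - grad_b) / abs(grad_b) > 1e-4) {
      warn("paf_delta_ci(): analytic and finite-difference gradients disagree")
    }
    if (pe_variance) {
      # per-participant influences: coefficient (sandwich) and Pe (cases)
      psi_beta <- as.vector(
        (fit$X * (fit$y - fit$fitted_mu)) %*%
          fit$bread[, info$term, drop = FALSE])
      psi_pe <- fit$y * (info$exposed_num - info$pe) / info$cases
      v_g <- sum((grad_b * psi_beta + 100 * (1 - exp(-beta)) * psi_pe)^2)
    } else {
      v_g <- grad_b^2 * fit$vcov_robust[info$term, info$term]
    }
    half <- Z975 * sqrt(v_g)
    tibble::tibble(
      exposure = ex, pe = info$pe, rr = exp(beta),
      excess_cases = info$pe * (exp(beta) - 1) / exp(beta) * info$cases,
      paf = g, conf_low = g - half, conf_high = g + half,
      method = "delta"
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("paf_result", class(out))
  out
}

#' Bootstrap confidence interval for the attributable fraction
#'
#' Percentile interval over seeded nonparametric resamples of participants;
#' each resample refits the model and re-evaluates the PAF. Resamples with
#' zero exposed cases are redrawn (the count is recorded in the
#' `n_redrawn` attribute).
#'
#' @inheritParams fit_modified_poisson
#' @param exposure Which exposure to evaluate (single column).
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @return A `paf_result` tibble with `method = "bootstrap"`; bootstrap
#'   draws are kept in the `draws` attribute.
#' @export
paf_bootstrap_ci <- function(data, outcome, exposures,
                             covariates = character(),
                             exposure = exposures[1],
                             ref_levels = NULL, B = 500L, seed = 1L) {
  if (B < 200) abort("paf_bootstrap_ci(): B must be >= 200")
  fit0 <- fit_modified_poisson(data, outcome, exposures, covariates,
                               ref_levels = ref_levels)
  point <- paf_delta_ci(fit0, data, exposure)
  set.seed(seed)
  n <- nrow(data)
  draws <- numeric(B)
  n_redrawn <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    res <- tryCatch({
      fitb <- fit_modified_poisson(boot, outcome, exposures, covariates,
                                   ref_levels = ref_levels)
      info <- exposure_info(fitb, boot, exposure)
      paf_of_beta(fitb$coefficients[[info$term]], info$pe)
    }, error = function(e) NA_real_)
    if (is.na(res)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > B) abort("paf_bootstrap_ci(): too many degenerate resamples")
      next
    }
    draws[b] <- res
    b <- b + 1L
  }
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  out <- point |>
    dplyr::mutate(conf_low = ci[1], conf_high = ci[2], method = "bootstrap")
  attr(out, "draws") <- draws
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("paf_result", class(out))
  out
}
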