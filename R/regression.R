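# Risk-ratio estimation: modified Poisson regression (log-link Poisson GLM on
# a binary outcome, fitted by IRLS) with a robust HC0/HC1 sandwich variance;
# closed-form 2x2 crude risk ratio; Pearson chi-square; VIF diagnostics.

Z975 <- 1.959964

#' Fit a modified Poisson regression
#'
#' Fits a Poisson GLM with log link to a binary outcome by iteratively
#' reweighted least squares (deviance tolerance 1e-8, at most 100
#' iterations) and pairs it with a robust sandwich variance
#' (bread = inverse Fisher information, meat = sum of score outer
#' products), the standard device for estimating risk ratios from binary
#' cohort data. Exposure and covariate columns are dummy-coded with
#' declared reference levels; exponentiated coefficients are risk ratios
#' with 95% CIs `exp(coef +/- 1.959964 * robust SE)`.
#'
#' @param data A data frame.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param exposures Character vector of exposure columns (factor or
#'   character); several exposures give a joint model.
#' @param covariates Character vector of adjustment columns.
#' @param ref_levels Optional named list `list(column = "level")` of
#'   reference levels; defaults to each factor's first level (`"high"` is
#'   used for the score-group factors, which carry levels high/low).
#' @param hc `"HC0"` (default) or `"HC1"` (multiplies the sandwich by
#'   n/(n - p)).
#' @return An object of class `rr_fit`: coefficients, `vcov_robust`,
#'   a `terms` tibble (term, estimate = log RR, rr, robust SE, CI, p),
#'   `n_used`, `converged`, `iterations`, plus the exposure-term map used by
#'   the attributable-fraction functions.
#' @seealso [crude_rr_2x2()], [paf_delta_ci()], [tidy.rr_fit()]
#' @export
fit_modified_poisson <- function(data, outcome, exposures,
                                 covariates = character(),
                                 ref_levels = NULL, hc = c("HC0", "HC1")) {
  hc <- match.arg(hc)
  cols <- c(outcome, exposures, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Unknown column(s): ", paste(missing_cols, collapse = ", ")))
  }
  use <- stats::complete.cases(data[cols])
  df <- data[use, cols, drop = FALSE]
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary (0/1 or logical)")

  for (col in c(exposures, covariates)) {
    f <- df[[col]]
    if (!is.factor(f)) f <- factor(f)
    ref <- ref_levels[[col]]
    if (!is.null(ref)) {
      if (!ref %in% levels(f)) abort(paste0("Reference level '", ref,
                                            "' not found in column ", col))
      f <- stats::relevel(f, ref)
    }
    df[[col]] <- droplevels(f)
  }
  rhs <- paste(c("1", c(exposures, covariates)), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }

  fit <- irls_poisson(X, y, tol = 1e-8, max_iter = 100L)
  beta <- fit$beta
  mu <- as.vector(exp(X %*% beta))

  info <- crossprod(X * mu, X)                 # Fisher information
  bread <- solve(info)
  score_resid <- X * (y - mu)
  meat <- crossprod(score_resid)
  vcov_robust <- bread %*% meat %*% bread
  if (hc == "HC1") vcov_robust <- vcov_robust * nrow(X) / (nrow(X) - ncol(X))
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))

  se <- unname(sqrt(diag(vcov_robust)))
  terms <- tibble::tibble(
    term = colnames(X),
    estimate = as.vector(beta),
    robust_se = se,
    rr = exp(as.vector(beta)),
    conf_low = exp(as.vector(beta) - Z975 * se),
    conf_high = exp(as.vector(beta) + Z975 * se),
    p_value = 2 * stats::pnorm(-abs(as.vector(beta) / se))
  )

  # map each exposure column to its non-reference dummy term(s)
  exposure_terms <- purrr::map(stats::setNames(exposures, exposures),
                               function(col) {
    levs <- levels(df[[col]])[-1]
    paste0(col, levs)
  })

  structure(list(
    coefficients = stats::setNames(as.vector(beta), colnames(X)),
    vcov_robust = vcov_robust, terms = terms,
    n_used = nrow(X), converged = fit$converged,
    iterations = fit$iterations, deviance = fit$deviance,
    outcome = outcome, exposures = exposures, covariates = covariates,
    exposure_terms = exposure_terms, hc = hc,
    exposure_levels = purrr::map(stats::setNames(exposures, exposures),
                                 ~ levels(df[[.x]])),
    # kept for influence-function delta intervals over derived quantities
    bread = bread, X = X, y = y, fitted_mu = mu
  ), class = "rr_fit")
}

irls_poisson <- function(X, y, tol = 1e-8, max_iter = 100L) {
  beta <- c(log(max(mean(y), 1e-8)), rep(0, ncol(X) - 1))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    w <- mu                                    # Poisson working weights
    z <- eta + (y - mu) / mu
    wX <- X * w
    beta <- solve(crossprod(wX, X), crossprod(wX, z))
    mu <- as.vector(exp(X %*% beta))
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev_old) && abs(dev_old - dev) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (!converged) warn("modified Poisson IRLS did not converge in max_iter")
  list(beta = beta, converged = converged, iterations = iter,
       deviance = dev_old)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("Modified Poisson fit (%s sandwich): n = %d, %d iteration(s)%s\n",
              x$hc, x$n_used, x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(dplyr::mutate(x$terms, dplyr::across(dplyr::where(is.numeric),
                                             ~ signif(.x, 4))))
  invisible(x)
}

#' Closed-form crude risk ratio from a 2x2 table
#'
#' `RR = (a/n1) / (c/n0)` with the standard log-scale Wald interval
#' `exp(log RR +/- 1.959964 * sqrt((1 - p1)/a + (1 - p0)/c))`.
#'
#' @param cases_exposed,n_exposed Cases and total in the exposed group.
#' @param cases_unexposed,n_unexposed Cases and total in the reference
#'   group.
#' @return A one-row tibble: `rr`, `conf_low`, `conf_high`, `log_rr`,
#'   `se_log_rr`, risks per arm.
#' @examples
#' crude_rr_2x2(847, 26414, 1224, 53857)  # RR 1.41 (1.29, 1.54)
#' @export
crude_rr_2x2 <- function(cases_exposed, n_exposed, cases_unexposed, n_unexposed) {
  counts <- c(cases_exposed, n_exposed, cases_unexposed, n_unexposed)
  if (any(counts <= 0)) {
    abort("All four counts must be positive (zero cells need continuity handling, out of scope)")
  }
  p1 <- cases_exposed / n_exposed
  p0 <- cases_unexposed / n_unexposed
  rr <- p1 / p0
  se <- sqrt((1 - p1) / cases_exposed + (1 - p0) / cases_unexposed)
  tibble::tibble(
    rr = rr, conf_low = rr * exp(-Z975 * se), conf_high = rr * exp(Z975 * se),
    log_rr = log(rr), se_log_rr = se,
    risk_exposed = p1, risk_unexposed = p0
  )
}

#' Expand aggregate 2x2 counts into participant-level rows
#'
#' Lets printed summary tables drive the regression path directly.
#'
#' @inheritParams crude_rr_2x2
#' @return A tibble with columns `exposure` (factor high/low, high =
#'   reference) and `case` (0/1), one row per participant.
#' @export
expand_counts <- function(cases_exposed, n_exposed, cases_unexposed, n_unexposed) {
  tibble::tibble(
    exposure = factor(rep(c("low", "high"), c(n_exposed, n_unexposed)),
                      levels = c("high", "low")),
    case = c(rep(1:0, c(cases_exposed, n_exposed - cases_exposed)),
             rep(1:0, c(cases_unexposed, n_unexposed - cases_unexposed)))
  )
}

#' Pearson chi-square test of a contingency table
#'
#' Classical Pearson statistic without continuity correction.
#'
#' @param table A matrix or table of counts (r x c).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("pearson_chi2(): zero marginal in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected <= 0)) abort("pearson_chi2(): nonpositive expected count")
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Variance inflation factors of dummy-coded covariates
#'
#' For each non-reference dummy column, regresses it on all other dummy
#' columns and reports `VIF = 1 / (1 - R^2)`; perfect collinearity yields
#' `Inf` with the offending term named.
#'
#' @param data A data frame.
#' @param columns Covariate columns to diagnose (>= 2 terms after dummy
#'   coding).
#' @return A tibble `term`, `vif`.
#' @export
vif_terms <- function(data, columns) {
  df <- data[stats::complete.cases(data[columns]), columns, drop = FALSE]
  for (col in columns) if (!is.factor(df[[col]])) df[[col]] <- factor(df[[col]])
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(columns, collapse = " + "))), data = df)[, -1, drop = FALSE]
  if (ncol(X) < 2) abort("vif_terms() needs >= 2 dummy-coded terms")
  vifs <- purrr::map_dbl(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Xo <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xo, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  out <- tibble::tibble(term = colnames(X), vif = vifs)
  if (any(is.infinite(vifs))) {
    warn(paste0("Perfect collinearity: ",
                paste(out$term[is.infinite(vifs)], collapse = ", ")))
  }
  out
}
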