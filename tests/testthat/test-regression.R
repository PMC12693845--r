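test_that("intercept-only model returns the prevalence exactly", {
  d <- tibble::tibble(y = rep(c(1, 0), c(30, 70)))
  fit <- fit_modified_poisson(d, "y", character())
  expect_equal(unname(exp(fit$coefficients[1])), 0.3, tolerance = 1e-10)
})

test_that("saturated binary-exposure fit equals the closed-form 2x2 result", {
  # several count configurations, including the bundled published ones
  cases <- list(c(847, 26414, 1224, 53857),
                c(1603, 60803, 468, 19468),
                c(50, 400, 30, 600))
  for (cc in cases) {
    closed <- crude_rr_2x2(cc[1], cc[2], cc[3], cc[4])
    d <- expand_counts(cc[1], cc[2], cc[3], cc[4])
    fit <- fit_modified_poisson(d, "case", "exposure")
    row <- fit$terms[fit$terms$term == "exposurelow", ]
    expect_equal(row$rr, closed$rr, tolerance = 1e-7)
    expect_equal(row$conf_low, closed$conf_low, tolerance = 1e-7)
    expect_equal(row$conf_high, closed$conf_high, tolerance = 1e-7)
  }
})

test_that("coefficients and robust variance match the reference GLM stack", {
  skip_if_not_installed("sandwich")
  co <- generate_cohort(simulation_config(5000, seed = 31))
  d <- dplyr::mutate(co, distress = rowSums(co[paste0("k6_", 1:6)]) >= 13)
  fit <- fit_modified_poisson(d, "distress", "pmds_group",
                              covariates = c("income", "smoking_maternal"))
  g <- stats::glm(distress ~ pmds_group + income + smoking_maternal,
                  family = stats::poisson(), data = d,
                  control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
               tolerance = 1e-7)
  v <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$vcov_robust), unname(v), tolerance = 1e-5)
  # HC1 applies the n/(n-p) factor
  fit1 <- fit_modified_poisson(d, "distress", "pmds_group",
                               covariates = c("income", "smoking_maternal"),
                               hc = "HC1")
  p <- length(fit$coefficients)
  expect_equal(fit1$vcov_robust,
               fit$vcov_robust * fit$n_used / (fit$n_used - p))
})

test_that("robust inference is invariant to symmetric label recoding", {
  d <- expand_counts(120, 1000, 80, 1000)
  fit <- fit_modified_poisson(d, "case", "exposure")
  flipped <- dplyr::mutate(
    d, exposure = factor(ifelse(exposure == "low", "high", "low"),
                         levels = c("high", "low")))
  fit2 <- fit_modified_poisson(flipped, "case", "exposure")
  r1 <- fit$terms[fit$terms$term == "exposurelow", ]
  r2 <- fit2$terms[fit2$terms$term == "exposurelow", ]
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)
  expect_equal(r1$robust_se, r2$robust_se, tolerance = 1e-8)
})

test_that("degenerate designs and outcomes are rejected with names", {
  d <- expand_counts(10, 100, 10, 100)
  d$dup <- d$exposure
  expect_error(fit_modified_poisson(d, "case", c("exposure", "dup")),
               "rank deficient.*dup")
  d2 <- dplyr::mutate(d, case = case + 1)
  expect_error(fit_modified_poisson(d2, "case", "exposure"), "binary")
})

test_that("reference levels can be redeclared", {
  d <- expand_counts(120, 1000, 80, 1000)
  fit <- fit_modified_poisson(d, "case", "exposure",
                              ref_levels = list(exposure = "low"))
  expect_true("exposurehigh" %in% fit$terms$term)
  expect_error(fit_modified_poisson(d, "case", "exposure",
                                    ref_levels = list(exposure = "nope")),
               "Reference level")
})

test_that("Pearson chi-square matches the published contrasts and the null", {
  counts <- example_distress_counts()
  p_of <- function(s) {
    row <- counts[counts$score == s, ]
    tab <- matrix(c(row$cases_low, row$n_low - row$cases_low,
                    row$cases_high, row$n_high - row$cases_high), nrow = 2,
                  byrow = TRUE)
    pearson_chi2(tab)$p_value
  }
  expect_lt(p_of("pmds"), 0.0001)
  expect_equal(round(p_of("mds"), 2), 0.08)
  expect_equal(round(p_of("rmed"), 2), 0.24)

  # table equal to its own expected counts: statistic 0, p = 1
  null_tab <- outer(c(30, 70), c(40, 60)) / 100
  res <- pearson_chi2(null_tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
})

test_that("variance inflation factors behave at the known limits", {
  set.seed(19)
  n <- 20000
  ind <- tibble::tibble(
    a = factor(sample(c("x", "y"), n, TRUE)),
    b = factor(sample(c("u", "v"), n, TRUE)),
    c = factor(sample(c("p", "q"), n, TRUE))
  )
  v <- vif_terms(ind, c("a", "b", "c"))
  expect_true(all(abs(v$vif - 1) < 0.02))

  dup <- dplyr::mutate(ind, a2 = a)
  expect_warning(vd <- vif_terms(dup, c("a", "a2", "b")), "collinearity")
  expect_true(any(is.infinite(vd$vif)))

  # binary pair with dummy correlation 0.9: VIF ~ 1/(1 - 0.81) = 5.26
  joint <- sample(c("11", "10", "01", "00"), n, replace = TRUE,
                  prob = c(0.475, 0.025, 0.025, 0.475))
  pair <- tibble::tibble(
    a = factor(substr(joint, 1, 1)),
    b = factor(substr(joint, 2, 2)),
    c = factor(sample(c("p", "q"), n, TRUE))
  )
  vp <- vif_terms(pair, c("a", "b", "c"))
  expect_equal(vp$vif[vp$term == "a1"], 1 / (1 - 0.81), tolerance = 0.2)
})
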