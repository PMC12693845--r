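test_that("attributable-fraction point formula has the right limits", {
  expect_equal(paf_point(0.5, 1), 0)
  expect_equal(paf_point(0.2, 1), 0)
  expect_equal(paf_point(1, 2), 50)
  expect_equal(paf_point(847 / 2071, 1.410945), 11.91, tolerance = 1e-3)
  # rr -> Inf approaches 100 * pe
  expect_equal(paf_point(0.7, 1e9), 70, tolerance = 1e-6)
  # negative for protective exposures, never truncated
  expect_lt(paf_point(0.3, 0.8), 0)
  expect_error(paf_point(1.2, 2), "\\[0, 1\\]")
  expect_error(paf_point(0.5, 0), "positive")
})

test_that("paf_point is monotone in rr and pe", {
  rrs <- seq(1.05, 4, length.out = 30)
  vals <- paf_point(0.4, rrs)
  expect_true(all(diff(vals) > 0))
  pes <- seq(0.05, 1, length.out = 30)
  vals2 <- paf_point(pes, 1.5)
  expect_true(all(diff(vals2) > 0))
})

test_that("Levin's population form is available for sensitivity analysis", {
  # with full exposure the two forms coincide
  expect_equal(paf_point(1, 2, form = "levin"), paf_point(1, 2))
  expect_equal(paf_point(0.4, 2, form = "levin"), 100 * 0.4 / 1.4)
  expect_equal(paf_point(0.3, 1, form = "levin"), 0)
})

test_that("delta-method interval is consistent with its ingredients", {
  d <- expand_counts(120, 1000, 60, 1200)
  fit <- fit_modified_poisson(d, "case", "exposure")
  res <- paf_delta_ci(fit, d)
  pe <- 120 / 180
  rr <- (120 / 1000) / (60 / 1200)
  expect_equal(res$pe, pe)
  expect_equal(res$rr, rr, tolerance = 1e-7)
  expect_equal(res$paf, paf_point(pe, rr), tolerance = 1e-6)
  expect_equal(res$excess_cases, pe * (rr - 1) / rr * 180, tolerance = 1e-6)
  expect_true(res$conf_low < res$paf && res$paf < res$conf_high)

  # the influence-function variance matches the closed-form delta on the
  # 2x2 counts (a, c binomial, PAF = (a - c n1/n0)/(a + c))
  a <- 120; c <- 60; n1 <- 1000; n0 <- 1200
  k <- n1 / n0
  p1 <- a / n1; p0 <- c / n0
  v_closed <- (1 + k)^2 * (c^2 * a * (1 - p1) + a^2 * c * (1 - p0)) /
    (a + c)^4 * 100^2
  se_got <- (res$conf_high - res$conf_low) / (2 * 1.959964)
  expect_equal(se_got, sqrt(v_closed), tolerance = 0.02)

  # conditioning on Pe: zero coefficient variance collapses the interval
  fit0 <- fit
  fit0$vcov_robust[] <- 0
  res0 <- paf_delta_ci(fit0, d, pe_variance = FALSE)
  expect_equal(res0$conf_low, res0$paf)
  expect_equal(res0$conf_high, res0$paf)
  # and the Pe-conditional interval is never wider than the full one
  resc <- paf_delta_ci(fit, d, pe_variance = FALSE)
  expect_lte(resc$conf_high - resc$conf_low, res$conf_high - res$conf_low)
})

test_that("analytic and finite-difference gradients agree on random fits", {
  set.seed(61)
  for (i in 1:25) {
    beta <- rnorm(1, 0.3, 0.5)
    pe <- runif(1, 0.05, 0.95)
    ga <- meddietpaf:::paf_grad_analytic(beta, pe)
    gf <- meddietpaf:::paf_grad_fd(beta, pe)
    expect_lt(abs(gf - ga) / abs(ga), 1e-4)
  }
})

test_that("bootstrap intervals are seeded-deterministic and need B >= 200", {
  d <- expand_counts(60, 500, 40, 700)
  b1 <- paf_bootstrap_ci(d, "case", "exposure", B = 200, seed = 5)
  b2 <- paf_bootstrap_ci(d, "case", "exposure", B = 200, seed = 5)
  expect_identical(b1$conf_low, b2$conf_low)
  expect_identical(b1$conf_high, b2$conf_high)
  expect_equal(b1$method, "bootstrap")
  expect_error(paf_bootstrap_ci(d, "case", "exposure", B = 100), ">= 200")
})

test_that("joint-exposure models yield one result per exposure and reduce to the single path", {
  co <- generate_cohort(simulation_config(8000, seed = 13))
  d <- dplyr::mutate(co, distress = rowSums(co[paste0("k6_", 1:6)]) >= 13)
  joint <- fit_modified_poisson(d, "distress", c("pmds_group", "mds_group"))
  resj <- paf_delta_ci(joint, d)
  expect_equal(nrow(resj), 2)
  expect_setequal(resj$exposure, c("pmds_group", "mds_group"))

  single <- fit_modified_poisson(d, "distress", "pmds_group")
  ress <- paf_delta_ci(single, d)
  single_as_joint <- paf_delta_ci(
    fit_modified_poisson(d, "distress", c("pmds_group")), d)
  expect_equal(single_as_joint, ress)
})

test_that("degenerate exposure strata are rejected", {
  d <- expand_counts(10, 100, 10, 100)
  fit <- fit_modified_poisson(d, "case", "exposure")
  d0 <- d
  d0$case[d0$exposure == "low"] <- 0
  expect_error(paf_delta_ci(fit, d0), "Pe undefined")
  expect_error(paf_delta_ci(fit, d, exposure = "nope"), "not present")
})
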