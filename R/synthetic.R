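# Seeded synthetic pregnancy cohorts with the statistical structure the
# analysis assumes: lognormal food-group intakes, categorical covariates
# drawn from realistic marginal frequencies, a log-linear binary distress
# outcome with configurable exposure risk ratio, and Kessler-6 items
# consistent with the generated outcome.

# Calibration constant: each pregnancy-score component meets its median
# cutoff with probability pnorm(PMDS_CALIBRATION_DELTA) = 0.580, which puts
# P(score <= 3 of 7) -- the low-adherence share -- at 0.329, the share the
# downstream analyses assume for their reference conditions.
PMDS_CALIBRATION_DELTA <- 0.2024139

#' Default per-component lognormal intake parameters
#'
#' Log-scale means and SDs for the synthetic intake generator. Means sit
#' `PMDS_CALIBRATION_DELTA` log-SDs above each component's default median
#' cutoff for beneficial components (below for meat), so that the simulated
#' low-adherence share of the 7-component pregnancy score is 0.329. Olive
#' oil and ethanol emulate a non-Mediterranean (Japanese-style) diet: olive
#' oil is rare, and ethanol is zero for 90% of the pregnant cohort with low
#' intakes among the remainder.
#'
#' @return A tibble with `component`, `meanlog`, `sdlog`.
#' @export
default_intake_params <- function() {
  cuts <- default_cutoffs()
  med <- cutoff_lookup(cuts, cuts$component, "median")
  d <- PMDS_CALIBRATION_DELTA
  sdl <- c(vegetables = 0.45, fruits_nuts = 0.55, legumes = 0.6, fish = 0.5,
           cereals = 0.35, meat = 0.5, dairy = 0.6)
  rows <- purrr::imap(sdl, function(s, g) {
    sign <- if (g == "meat") -1 else 1
    tibble::tibble(component = g, meanlog = log(med[[g]]) + sign * d * s,
                   sdlog = s)
  }) |> unname()
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    # olive oil scarce; MUFA/SFA ratio lognormal with P(ratio >= 1.3) = 0.15
    tibble::tibble(component = "olive_oil", meanlog = log(0.5), sdlog = 1.0),
    tibble::tibble(component = "sfa", meanlog = log(20), sdlog = 0.3),
    tibble::tibble(component = "mufa", meanlog = log(20) - 0.1774, sdlog = 0.3),
    # ethanol parameters apply to the drinking minority only
    tibble::tibble(component = "ethanol", meanlog = log(0.8), sdlog = 1.0)
  )
}

# Marginal level frequencies for the categorical covariates (first level is
# the reference). Probabilities are renormalised over observed levels.
covariate_marginals <- function() {
  norm <- function(x) x / sum(x)
  purrr::map(list(
    age_mt1 = c("20-34.9 years" = 0.746, "<20 years" = 0.011, ">=35 years" = 0.242),
    bmi_prepreg = c("Normal range" = 0.735, "Underweight" = 0.161, "Overweight" = 0.104),
    parity = c("Multiparity" = 0.573, "Nulliparity" = 0.427),
    multiple_pregnancy = c("Singleton" = 0.990, "Multiple" = 0.010),
    conception_method = c("Spontaneous pregnancy" = 0.930, "Non-ART" = 0.038, "ART" = 0.032),
    dm_gdm = c("No" = 0.971, "Yes" = 0.029),
    alcohol_status = c("Never or quit" = 0.899, "Continue drinking" = 0.101),
    smoking_maternal = c("Not currently smoking" = 0.957, "Currently smoking" = 0.043),
    smoking_paternal = c("Not currently smoking" = 0.535, "Currently smoking" = 0.465),
    marital_status = c("Married" = 0.957, "Unmarried" = 0.036, "Divorced or widowed" = 0.008),
    employment_status = c("Not working" = 0.362, "Working" = 0.638),
    edu_maternal = c("College" = 0.648, "High school" = 0.310, "Junior high school" = 0.043),
    edu_paternal = c("College" = 0.567, "High school" = 0.364, "Junior high school" = 0.069),
    income = c("200-399" = 0.339, "<200" = 0.053, "400-599" = 0.333, ">=600" = 0.274),
    region = c("Tohoku" = 0.220, "Hokkaido" = 0.081, "Kanto" = 0.119, "Chubu" = 0.182,
               "Kinki" = 0.166, "Chugoku" = 0.029, "Shikoku" = 0.070, "Kyusyu-Okinawa" = 0.133),
    mds_mt1 = c("high" = 0.243, "low" = 0.757)
  ), norm)
}

#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of [generate_cohort()] with study-condition defaults:
#' reference-stratum (high-adherence) distress risk 2.3%, exposure risk
#' ratio 1.41 for the low pregnancy-score group, a low-adherence share
#' calibrated to 32.9%, and energy intake Normal(1735, 759) kcal/day, which
#' together give an overall distress prevalence near 2.6%.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; fully determines the generated table.
#' @param baseline_risk Distress risk in the reference stratum (high
#'   pregnancy-score adherence, covariates at reference levels).
#' @param true_rr_low_pmds Risk ratio for the low-adherence group (>= 0).
#' @param covariate_effects Named list: `list(column = c(level = log_rr))`.
#'   Participants at `level` of `column` have their log-risk shifted by
#'   `log_rr`.
#' @param covariate_intake_shift Named list with the same shape, giving a
#'   shift (in log-SD units) applied to the beneficial food-group log-means
#'   (and with opposite sign to meat) for participants at that covariate
#'   level. Nonzero values make diet adherence depend on the covariate,
#'   which is how confounded scenarios are planted.
#' @param intake_params Per-component lognormal parameters
#'   ([default_intake_params()]).
#' @param cutoffs Cutoff table used to score the simulated intakes and
#'   assign exposure groups ([default_cutoffs()]).
#' @param energy_mean_sd Mean and SD of daily energy intake (kcal/day).
#' @param p_drinker Probability of any ethanol intake.
#' @param missingness_rates Named per-column missingness probabilities
#'   applied via [inject_missingness()]; default none.
#' @param flag_rates Rates for the exclusion-cascade flags: repeat
#'   participation, abortion/stillbirth, mental-illness history.
#' @param k6_nondistress_probs Category probabilities (<=4, 5-9, 10-12) for
#'   K6 totals of non-distressed participants.
#' @param k6_distress_size,k6_distress_prob Binomial spread of distressed
#'   totals above the 13-point cutoff.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_participants,
                              seed = 1L,
                              baseline_risk = 0.023,
                              true_rr_low_pmds = 1.41,
                              covariate_effects = list(),
                              covariate_intake_shift = list(),
                              intake_params = default_intake_params(),
                              cutoffs = default_cutoffs(),
                              energy_mean_sd = c(1734.95, 759.475),
                              p_drinker = 0.10,
                              missingness_rates = NULL,
                              flag_rates = c(repeat_participation = 0.064,
                                             abortion_stillbirth = 0.035,
                                             mental_illness_history = 0.06),
                              k6_nondistress_probs = c(0.7495, 0.1868, 0.0637),
                              k6_distress_size = 11,
                              k6_distress_prob = 0.15) {
  stopifnot(n_participants >= 1,
            baseline_risk >= 0, baseline_risk <= 1,
            true_rr_low_pmds >= 0,
            all(flag_rates >= 0 & flag_rates <= 1))
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    baseline_risk = baseline_risk, true_rr_low_pmds = true_rr_low_pmds,
    covariate_effects = covariate_effects,
    covariate_intake_shift = covariate_intake_shift,
    intake_params = intake_params, cutoffs = cutoffs,
    energy_mean_sd = energy_mean_sd, p_drinker = p_drinker,
    missingness_rates = missingness_rates, flag_rates = flag_rates,
    k6_nondistress_probs = k6_nondistress_probs / sum(k6_nondistress_probs),
    k6_distress_size = k6_distress_size, k6_distress_prob = k6_distress_prob
  ), class = "simulation_config")
}

# allocate K6 totals across 6 items bounded 0..4 by multivariate
# hypergeometric sampling over the 24 point-slots (4 per item)
allocate_k6_items <- function(total) {
  n <- length(total)
  items <- matrix(0L, n, 6)
  remaining <- total
  slots_left <- 24L
  for (j in 1:5) {
    slots_left <- slots_left - 4L
    items[, j] <- stats::rhyper(n, m = 4L, n = slots_left, k = remaining)
    remaining <- remaining - items[, j]
  }
  items[, 6] <- remaining
  items
}

per_level_lookup <- function(spec, data) {
  # spec: list(column = c(level = value)); returns per-row summed values
  out <- numeric(nrow(data))
  for (col in names(spec)) {
    if (!col %in% names(data)) {
      abort(paste0("Unknown covariate column in config: ", col))
    }
    vals <- spec[[col]]
    for (lev in names(vals)) {
      hit <- !is.na(data[[col]]) & data[[col]] == lev
      out[hit] <- out[hit] + vals[[lev]]
    }
  }
  out
}

#' Generate a synthetic pregnancy cohort
#'
#' Draws per-participant food-group intakes (lognormal), energy, categorical
#' covariates (marginal frequencies), exposure groups obtained by actually
#' scoring the simulated intakes against the configured cutoffs, a binary
#' distress outcome from a log-linear risk model, and six Kessler-6 items
#' consistent with the outcome (items sum to >= 13 exactly for generated
#' cases). Identical configurations produce identical tables.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per participant: `participant_id`, food
#'   group intakes (g/day), `mufa_g`, `sfa_g`, `ethanol_g`, `energy_kcal`,
#'   covariate factors, exclusion-cascade flags, K6 items `k6_1..k6_6`, and
#'   the scored convenience columns `mds_group`, `rmed_group`, `pmds_group`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  set.seed(config$seed)

  # covariates first (intake shifts may depend on them)
  marg <- covariate_marginals()
  cov_tbl <- purrr::imap(marg, function(p, nm) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }) |> tibble::as_tibble()

  shift <- per_level_lookup(config$covariate_intake_shift, cov_tbl)

  ip <- config$intake_params
  par_of <- function(comp) ip[ip$component == comp, ]
  draw <- function(comp, shift_sign = 0) {
    p <- par_of(comp)
    stats::rlnorm(n, meanlog = p$meanlog + shift_sign * shift * p$sdlog,
                  sdlog = p$sdlog)
  }
  intake <- tibble::tibble(
    participant_id = sprintf("P%07d", seq_len(n)),
    vegetables  = draw("vegetables", 1),
    fruits_nuts = draw("fruits_nuts", 1),
    legumes     = draw("legumes", 1),
    fish        = draw("fish", 1),
    cereals     = draw("cereals", 1),
    meat        = draw("meat", -1),
    dairy       = draw("dairy", 1),
    olive_oil   = draw("olive_oil"),
    mufa_g      = draw("mufa"),
    sfa_g       = draw("sfa"),
    ethanol_g   = (stats::runif(n) < config$p_drinker) * draw("ethanol"),
    energy_kcal = stats::rnorm(n, config$energy_mean_sd[1], config$energy_mean_sd[2])
  )
  intake$energy_kcal <- pmax(intake$energy_kcal, 50)

  scores <- score_diet(intake, config$cutoffs)
  low_pmds <- scores$pmds_group == "low"

  log_risk <- log(config$baseline_risk) +
    log(config$true_rr_low_pmds) * as.numeric(low_pmds) +
    per_level_lookup(config$covariate_effects, cov_tbl)
  risk <- exp(log_risk)
  if (any(risk > 1)) {
    i <- which.max(risk)
    strat <- paste(purrr::imap_chr(as.list(cov_tbl[i, ]), function(v, nm)
      paste0(nm, "=", as.character(v))), collapse = ", ")
    abort(paste0("Outcome risk exceeds 1 (", signif(max(risk), 4),
                 ") in stratum: low_pmds=", low_pmds[i], ", ", strat))
  }
  distress <- stats::rbinom(n, 1, risk) == 1

  # K6 totals consistent with the outcome class, then items
  cat_nd <- sample.int(3, n, replace = TRUE, prob = config$k6_nondistress_probs)
  lo <- c(0L, 5L, 10L)[cat_nd]
  hi <- c(4L, 9L, 12L)[cat_nd]
  total_nd <- lo + floor(stats::runif(n) * (hi - lo + 1))
  total_d <- 13L + stats::rbinom(n, config$k6_distress_size, config$k6_distress_prob)
  total <- total_nd
  total[distress] <- total_d[distress]
  items <- allocate_k6_items(as.integer(total))
  colnames(items) <- paste0("k6_", 1:6)

  fr <- config$flag_rates
  flags <- tibble::tibble(
    repeat_participation = stats::runif(n) < fr[["repeat_participation"]],
    abortion_stillbirth = stats::runif(n) < fr[["abortion_stillbirth"]],
    mental_illness_history = stats::runif(n) < fr[["mental_illness_history"]]
  )

  out <- dplyr::bind_cols(
    intake, cov_tbl, flags, tibble::as_tibble(items),
    scores[c("mds_group", "rmed_group", "pmds_group")]
  )
  if (!is.null(config$missingness_rates)) {
    out <- inject_missingness(out, config$missingness_rates,
                              seed = config$seed + 1L)
  }
  out
}

#' Inject missing-completely-at-random cells
#'
#' Masks cells of the named columns independently with the given
#' probabilities. Observed cells are never altered.
#'
#' @param table A data frame.
#' @param rates Named numeric vector or list of per-column missingness
#'   probabilities in \[0, 1\].
#' @param seed Integer seed for the masking draws.
#' @return The table with masked cells set to `NA`.
#' @examples
#' inject_missingness(tibble::tibble(a = 1:10), c(a = 0.5), seed = 1)
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) {
    abort("Missingness rates must lie in [0, 1]")
  }
  bad <- setdiff(names(rates), names(table))
  if (length(bad) > 0) {
    abort(paste0("Unknown column(s) in missingness rates: ",
                 paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  for (col in names(rates)) {
    mask <- stats::runif(nrow(table)) < rates[[col]]
    table[[col]][mask] <- NA
  }
  table
}

#' Expected low-adherence share of the pregnancy score
#'
#' Closed-form share of participants in the low group (score <= 3 of 7)
#' implied by a configuration with no covariate-dependent intake shifts:
#' each component meets its cutoff independently with a normal-tail
#' probability, so the score is Poisson-binomial.
#'
#' @param config A [simulation_config()].
#' @return Probability in \[0, 1\].
#' @export
expected_low_pmds_share <- function(config) {
  ip <- config$intake_params
  med <- cutoff_lookup(config$cutoffs, config$cutoffs$component, "median")
  p_comp <- purrr::map_dbl(c(PMDS_BENEFICIAL, PMDS_DETRIMENTAL), function(g) {
    row <- ip[ip$component == g, ]
    p_ge <- stats::pnorm((row$meanlog - log(med[[g]])) / row$sdlog)
    if (g == "meat") 1 - p_ge else p_ge   # meat scores when below the cutoff
  })
  # Poisson-binomial P(sum <= 3) by convolution
  pmf <- 1
  for (p in p_comp) pmf <- convolve_bernoulli(pmf, p)
  sum(pmf[1:4])
}

convolve_bernoulli <- function(pmf, p) {
  c(pmf * (1 - p), 0) + c(0, pmf * p)
}

#' Write a cohort CSV with a provenance sidecar
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path; a `<path>.provenance.json` sidecar records
#'   the seed and generator settings.
#' @param config The [simulation_config()] that produced the cohort (or
#'   `NULL` for ingested data).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  if (!requireNamespace("readr", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_cohort() needs the readr and jsonlite packages")
  }
  readr::write_csv(cohort, path)
  prov <- list(
    n_rows = nrow(cohort),
    seed = if (!is.null(config)) config$seed else NA,
    baseline_risk = if (!is.null(config)) config$baseline_risk else NA,
    true_rr_low_pmds = if (!is.null(config)) config$true_rr_low_pmds else NA,
    written = "meddietpaf::write_cohort"
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
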