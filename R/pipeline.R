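# End-to-end orchestration: cohort (synthetic, supplied, or aggregate
# counts) -> scores -> selection -> imputation -> models -> attributable
# fractions, emitting report tables shaped like the ones such studies print.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a participant-level `cohort`
#' tibble, a [simulation_config()] in `sim`, or an aggregate `counts` table
#' shaped like [example_distress_counts()].
#'
#' @param cohort Optional participant-level cohort tibble (intakes, K6
#'   items, covariates, exclusion flags).
#' @param sim Optional [simulation_config()] used to generate the cohort.
#' @param counts Optional aggregate 2x2 counts per score.
#' @param cutoffs Cutoff table, or `"within_sample"` to derive medians and
#'   tertiles from the analysed cohort with [derive_cutoffs()].
#' @param scores Which adherence indices to analyse.
#' @param energy_bounds Closed kcal/day plausibility window; `NULL`
#'   recomputes mean +/- 2 SD from the data.
#' @param covariates Adjustment covariate columns; default: every
#'   generator covariate present in the cohort. `character(0)` disables the
#'   adjusted model.
#' @param impute_k Neighbours for covariate imputation (`NULL` disables).
#' @param joint_pairs List of score pairs fitted jointly (both exposures in
#'   one adjusted model).
#' @param seed Integer seed recorded in the report and used for imputation
#'   tie-breaks.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, sim = NULL, counts = NULL,
                            cutoffs = default_cutoffs(),
                            scores = c("mds", "rmed", "pmds"),
                            energy_bounds = NULL,
                            covariates = NULL,
                            impute_k = 5L,
                            joint_pairs = list(c("pmds", "mds"),
                                               c("pmds", "rmed"),
                                               c("mds", "rmed")),
                            seed = 1L) {
  n_src <- sum(!is.null(cohort), !is.null(sim), !is.null(counts))
  if (n_src != 1) abort("Exactly one of cohort, sim, counts must be supplied")
  structure(list(cohort = cohort, sim = sim, counts = counts,
                 cutoffs = cutoffs, scores = scores,
                 energy_bounds = energy_bounds, covariates = covariates,
                 impute_k = impute_k, joint_pairs = joint_pairs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Participant-level mode: scores the intakes against the cutoffs, scores
#' the Kessler-6 items, applies the exclusion cascade, imputes missing
#' categorical covariates, then fits crude and adjusted modified Poisson
#' models per adherence index, joint two-score models per configured pair,
#' and attributable fractions with delta-method CIs. Aggregate-count mode:
#' reproduces the crude contrasts (closed form and regression path) from a
#' 2x2 counts table.
#'
#' @param config A [pipeline_config()].
#' @return A `meddiet_report` list: `baseline_table`, `k6_table`,
#'   `rr_table`, `paf_table`, `joint_table`, `attrition`, `fits`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$counts)) return(run_counts_pipeline(config))

  cohort <- if (!is.null(config$sim)) generate_cohort(config$sim) else config$cohort
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  cutoffs <- config$cutoffs
  if (identical(cutoffs, "within_sample")) {
    cutoffs <- stage("derive_cutoffs", derive_cutoffs(cohort))
  }

  cohort <- stage("scoring", {
    drop <- intersect(c("mds_group", "rmed_group", "pmds_group"), names(cohort))
    sc <- score_diet(cohort, cutoffs, scores = config$scores)
    dplyr::left_join(dplyr::select(cohort, -dplyr::all_of(drop)), sc,
                     by = "participant_id")
  })
  cohort <- stage("k6", {
    dplyr::left_join(cohort,
                     score_k6(cohort[c("participant_id", paste0("k6_", 1:6))]),
                     by = "participant_id")
  })

  sel <- stage("selection", apply_exclusions(
    cohort, energy_bounds = config$energy_bounds,
    exposure_cols = paste0(config$scores, "_group")))
  analysis <- sel$cohort

  covariates <- config$covariates %||%
    intersect(names(covariate_marginals()), names(analysis))
  audit <- NULL
  if (!is.null(config$impute_k) && length(covariates) > 0) {
    imp <- stage("imputation", impute_knn(analysis, covariates,
                                          k = config$impute_k,
                                          seed = config$seed))
    analysis <- imp$table
    audit <- imp$audit
  }

  group_cols <- paste0(config$scores, "_group")
  baseline_table <- stage("baseline_table",
                          baseline_characteristics(analysis, covariates, group_cols))
  k6_table <- stage("k6_table", k6_by_group(analysis, config$scores))

  fits <- list()
  rr_rows <- list()
  paf_rows <- list()
  for (s in config$scores) {
    gcol <- paste0(s, "_group")
    crude <- stage(paste0("crude_", s),
                   fit_modified_poisson(analysis, "distress", gcol))
    fits[[paste0(s, "_crude")]] <- crude
    rr_rows[[length(rr_rows) + 1]] <- rr_report_row(crude, s, "crude", gcol)
    paf_rows[[length(paf_rows) + 1]] <- paf_delta_ci(crude, analysis, gcol) |>
      dplyr::mutate(score = s, model = "crude")
    if (length(covariates) > 0) {
      adj <- stage(paste0("adjusted_", s),
                   fit_modified_poisson(analysis, "distress", gcol, covariates))
      fits[[paste0(s, "_adjusted")]] <- adj
      rr_rows[[length(rr_rows) + 1]] <- rr_report_row(adj, s, "adjusted", gcol)
      paf_rows[[length(paf_rows) + 1]] <- paf_delta_ci(adj, analysis, gcol) |>
        dplyr::mutate(score = s, model = "adjusted")
    }
  }

  joint_rows <- list()
  for (pair in config$joint_pairs) {
    if (!all(pair %in% config$scores)) next
    gcols <- paste0(pair, "_group")
    jt <- stage(paste0("joint_", paste(pair, collapse = "_")),
                fit_modified_poisson(analysis, "distress", gcols, covariates))
    fits[[paste0("joint_", paste(pair, collapse = "_"))]] <- jt
    pafj <- paf_delta_ci(jt, analysis)
    for (i in seq_along(pair)) {
      row <- rr_report_row(jt, pair[i], "joint", gcols[i]) |>
        dplyr::mutate(pair = paste(pair, collapse = "+"))
      joint_rows[[length(joint_rows) + 1]] <- dplyr::left_join(
        row,
        dplyr::select(pafj, "exposure", "paf", paf_low = "conf_low",
                      paf_high = "conf_high"),
        by = "exposure")
    }
  }

  report <- structure(list(
    baseline_table = baseline_table,
    k6_table = k6_table,
    rr_table = dplyr::bind_rows(rr_rows),
    paf_table = dplyr::bind_rows(paf_rows) |>
      dplyr::relocate("score", "model"),
    joint_table = if (length(joint_rows)) dplyr::bind_rows(joint_rows) else NULL,
    attrition = sel$attrition,
    imputation_audit = audit,
    fits = fits,
    cutoffs = cutoffs,
    n_analysis = nrow(analysis),
    seed = config$seed,
    config_hash = rlang::hash(config)
  ), class = "meddiet_report")
  report
}

run_counts_pipeline <- function(config) {
  counts <- config$counts
  rows <- purrr::pmap(counts, function(score, cases_low, n_low, cases_high, n_high) {
    closed <- crude_rr_2x2(cases_low, n_low, cases_high, n_high)
    expanded <- expand_counts(cases_low, n_low, cases_high, n_high)
    fit <- fit_modified_poisson(expanded, "case", "exposure")
    reg <- fit$terms[fit$terms$term == "exposurelow", ]
    pe <- cases_low / (cases_low + cases_high)
    tibble::tibble(
      score = score, model = "crude",
      rr = closed$rr, conf_low = closed$conf_low, conf_high = closed$conf_high,
      rr_regression = reg$rr, conf_low_regression = reg$conf_low,
      conf_high_regression = reg$conf_high,
      pe = pe, paf = paf_point(pe, closed$rr)
    )
  })
  structure(list(
    baseline_table = NULL, k6_table = NULL,
    rr_table = dplyr::bind_rows(rows),
    paf_table = dplyr::bind_rows(rows)[c("score", "model", "pe", "paf")],
    joint_table = NULL, attrition = NULL, fits = NULL,
    # the per-score rows describe the same cohort, not disjoint samples
    n_analysis = max(counts$n_low + counts$n_high),
    seed = config$seed, config_hash = rlang::hash(config)
  ), class = "meddiet_report")
}

rr_report_row <- function(fit, score, model, gcol) {
  term <- fit$exposure_terms[[gcol]]
  row <- fit$terms[fit$terms$term == term, ]
  tibble::tibble(score = score, model = model, exposure = gcol,
                 term = term, rr = row$rr, conf_low = row$conf_low,
                 conf_high = row$conf_high, p_value = row$p_value,
                 n_used = fit$n_used)
}

baseline_characteristics <- function(analysis, covariates, group_cols) {
  if (length(covariates) == 0) {
    return(tibble::tibble(score = character(0), covariate = character(0),
                          level = character(0), group = factor(character(0)),
                          n = integer(0), pct = numeric(0)))
  }
  purrr::map(group_cols, function(gcol) {
    purrr::map(covariates, function(cov) {
      analysis |>
        dplyr::filter(!is.na(.data[[gcol]])) |>
        dplyr::count(group = .data[[gcol]], level = .data[[cov]]) |>
        dplyr::group_by(.data$group) |>
        dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
        dplyr::ungroup() |>
        dplyr::mutate(score = sub("_group$", "", gcol), covariate = cov,
                      level = as.character(.data$level))
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("score", "covariate", "level", "group")
}

k6_by_group <- function(analysis, scores) {
  purrr::map(scores, function(s) {
    gcol <- paste0(s, "_group")
    df <- analysis |> dplyr::filter(!is.na(.data[[gcol]]), !is.na(.data$k6_category))
    tab <- df |>
      dplyr::count(group = .data[[gcol]], k6_category = .data$k6_category,
                   .drop = FALSE) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    two_by_two <- table(df[[gcol]] == "low", df$distress)
    p <- pearson_chi2(two_by_two)$p_value
    dplyr::mutate(tab, score = s, p_distress = p) |>
      dplyr::relocate("score")
  }) |> dplyr::bind_rows()
}

#' @export
print.meddiet_report <- function(x, ...) {
  cat("Diet-adherence / distress analysis report\n")
  cat(sprintf("  analysis n = %d, seed = %d, config hash %s\n",
              x$n_analysis, x$seed, substr(x$config_hash, 1, 10)))
  if (!is.null(x$attrition)) print(x$attrition)
  cat("\nRisk ratios (low vs high adherence):\n")
  print(dplyr::mutate(x$rr_table, dplyr::across(dplyr::where(is.numeric),
                                                ~ round(.x, 3))))
  cat("\nAttributable fractions (%):\n")
  print(dplyr::mutate(x$paf_table, dplyr::across(dplyr::where(is.numeric),
                                                 ~ round(.x, 2))))
  invisible(x)
}
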