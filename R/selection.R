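# Participant-exclusion cascade and attrition accounting.

#' Sample-based energy-intake bounds
#'
#' Mean +/- 2 sample standard deviations (denominator n - 1) of daily energy
#' intake, the rule behind a printed plausibility interval such as
#' 216.0-3253.9 kcal/day.
#'
#' @param energy Numeric vector of energy intakes (kcal/day); NAs dropped.
#' @return Length-2 numeric `c(lo, hi)`.
#' @examples
#' energy_sd_bounds(c(1800, 2200))
#' @export
energy_sd_bounds <- function(energy) {
  energy <- energy[!is.na(energy)]
  if (length(energy) < 2) abort("energy_sd_bounds() needs >= 2 observations")
  m <- mean(energy)
  s <- stats::sd(energy)
  c(m - 2 * s, m + 2 * s)
}

#' Apply the participant-exclusion cascade
#'
#' Filters a raw cohort in the documented order and logs each step:
#' (1) keep first participation only; (2) drop abortion/stillbirth;
#' (3) drop missing or improbable exposure/outcome data; (4) drop energy
#' intake outside the closed interval `energy_bounds`; (5) drop history of
#' mental illness. A participant triggering several criteria is attributed
#' to the first step that catches them.
#'
#' @param cohort A cohort tibble with logical flag columns
#'   `repeat_participation`, `abortion_stillbirth`,
#'   `mental_illness_history`, the column `energy_kcal`, and the
#'   exposure/outcome columns named in `exposure_cols` / `outcome_cols`.
#' @param energy_bounds Closed `c(lo, hi)` kcal/day interval; rows outside
#'   are excluded. `NULL` (default) recomputes mean +/- 2 SD from the data
#'   remaining after step 3 via [energy_sd_bounds()].
#' @param exposure_cols,outcome_cols Columns whose missingness excludes a
#'   participant at step 3. Defaults cover the three score groups and the
#'   six K6 items.
#' @param improbable Optional list of predicate functions `f(cohort)`
#'   returning a logical "improbable" flag per row; default none.
#' @return A list with `cohort` (retained rows) and `attrition`, a tibble of
#'   class `attrition_log` with columns `filter`, `n_before`, `n_excluded`,
#'   `n_after`.
#' @export
apply_exclusions <- function(cohort,
                             energy_bounds = NULL,
                             exposure_cols = intersect(
                               c("mds_group", "rmed_group", "pmds_group"),
                               names(cohort)),
                             outcome_cols = intersect(paste0("k6_", 1:6),
                                                      names(cohort)),
                             improbable = NULL) {
  needed <- c("repeat_participation", "abortion_stillbirth",
              "mental_illness_history", "energy_kcal")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  steps <- list()
  note <- function(name, keep) {
    n0 <- nrow(cohort)
    cohort <<- cohort[keep, , drop = FALSE]
    steps[[length(steps) + 1]] <<- tibble::tibble(
      filter = name, n_before = n0, n_excluded = n0 - nrow(cohort),
      n_after = nrow(cohort))
  }

  note("first_participation_only", !isTRUE_vec(cohort$repeat_participation))
  note("abortion_stillbirth", !isTRUE_vec(cohort$abortion_stillbirth))

  miss <- rep(FALSE, nrow(cohort))
  for (col in c(exposure_cols, outcome_cols)) miss <- miss | is.na(cohort[[col]])
  miss <- miss | is.na(cohort$energy_kcal)
  if (!is.null(improbable)) {
    for (f in improbable) miss <- miss | isTRUE_vec(f(cohort))
  }
  note("missing_or_improbable_data", !miss)

  if (is.null(energy_bounds)) energy_bounds <- energy_sd_bounds(cohort$energy_kcal)
  note("energy_outside_bounds",
       cohort$energy_kcal >= energy_bounds[1] & cohort$energy_kcal <= energy_bounds[2])
  note("mental_illness_history", !isTRUE_vec(cohort$mental_illness_history))

  attrition <- dplyr::bind_rows(steps)
  class(attrition) <- c("attrition_log", class(attrition))
  attr(attrition, "energy_bounds") <- energy_bounds
  list(cohort = cohort, attrition = attrition)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.attrition_log <- function(x, ...) {
  cat("Participant exclusion cascade\n")
  b <- attr(x, "energy_bounds")
  if (!is.null(b)) {
    cat(sprintf("  energy window: %.1f-%.1f kcal/day\n", b[1], b[2]))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %7d -> %7d  (-%d)\n", x$filter[i], x$n_before[i],
                x$n_after[i], x$n_excluded[i]))
  }
  invisible(x)
}
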