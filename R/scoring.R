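# Adherence indices: 9-component median-cutoff score (0-9, "mds"),
# tertile-based score (0-18, "rmed"), and the 7-component pregnancy variant
# (0-7, "pmds").
#
# Boundary conventions (applied uniformly):
#   * median components: "at or above the median" counts as meeting the
#     cutoff, so beneficial components score 1 iff intake >= median and
#     detrimental components score 1 iff intake < median;
#   * tertile components: lower-closed intervals [0, t1), [t1, t2), [t2, Inf),
#     so an intake exactly at t1 falls in the second tertile;
#   * alcohol: closed ethanol window [5, 25] g/day.

median_point <- function(x, cutoff, beneficial = TRUE) {
  if (beneficial) as.integer(x >= cutoff) else as.integer(x < cutoff)
}

tertile_point <- function(x, t1, t2, beneficial = TRUE) {
  asc <- (x >= t1) + (x >= t2)          # lower-closed intervals
  as.integer(if (beneficial) asc else 2L - asc)
}

alcohol_point <- function(ethanol_g, window = alcohol_window(), points = 1L) {
  as.integer(points * (ethanol_g >= window[1] & ethanol_g <= window[2]))
}

grouped <- function(points, threshold) {
  factor(c("low", "high")[(points >= threshold) + 1L],
         levels = c("high", "low"))
}

score_frame <- function(intake, sub, prefix, threshold) {
  points <- Reduce(`+`, sub)
  reason <- rep(NA_character_, nrow(intake))
  for (nm in names(sub)) {
    if (anyNA(sub[[nm]])) {
      hit <- is.na(sub[[nm]]) & is.na(reason)
      reason[hit] <- paste0("missing_", nm)
    }
  }
  out <- tibble::tibble(participant_id = intake$participant_id)
  for (nm in names(sub)) out[[paste0(prefix, "_", nm)]] <- sub[[nm]]
  out[[paste0(prefix, "_points")]] <- points
  out[[paste0(prefix, "_group")]] <- grouped(points, threshold)
  out[[paste0(prefix, "_reason")]] <- reason
  out
}

#' Nine-component Mediterranean adherence score (median cutoffs)
#'
#' Scores each of nine components 0/1 against per-component median cutoffs:
#' vegetables, fruits+nuts, legumes, fish and cereals score 1 at or above the
#' median; the MUFA/SFA fat ratio scores 1 at or above its median; meat and
#' dairy (detrimental) score 1 below the median; ethanol scores 1 inside the
#' 5-25 g/day window. Totals run 0-9; participants with >= 5 points form the
#' high-adherence group, <= 4 the low group. A participant missing any
#' component (including an undefined fat ratio when SFA is 0) receives `NA`
#' points and a reason code.
#'
#' @param intake A tibble of per-participant daily intakes with columns
#'   `participant_id`, the food groups in g/day, `mufa_g`, `sfa_g`,
#'   `ethanol_g`.
#' @param cutoffs A cutoff table as from [default_cutoffs()] or
#'   [derive_cutoffs()]; must carry a `median` for the food groups and
#'   `fat_ratio`.
#' @param window Closed ethanol window in g/day, default `c(5, 25)`.
#' @return A tibble with per-component 0/1 sub-scores (`mds_*`),
#'   `mds_points`, `mds_group` (factor, levels high/low with high as
#'   reference) and `mds_reason`.
#' @examples
#' score_mds(
#'   tibble::tibble(participant_id = 1, vegetables = 300, fruits_nuts = 250,
#'     legumes = 70, fish = 90, cereals = 320, meat = 80, dairy = 120,
#'     olive_oil = 12, mufa_g = 30, sfa_g = 20, ethanol_g = 10),
#'   default_cutoffs()
#' )
#' @export
score_mds <- function(intake, cutoffs = default_cutoffs(),
                      window = alcohol_window()) {
  comps <- c(MDS_BENEFICIAL, "fat_ratio", MDS_DETRIMENTAL)
  check_cutoffs(cutoffs, comps, "median")
  med <- cutoff_lookup(cutoffs, comps, "median")
  ratio <- fat_ratio(intake$mufa_g, intake$sfa_g)
  sub <- c(
    lapply(stats::setNames(MDS_BENEFICIAL, MDS_BENEFICIAL), function(g) {
      median_point(intake[[g]], med[[g]], beneficial = TRUE)
    }),
    list(fat_ratio = median_point(ratio, med[["fat_ratio"]], beneficial = TRUE)),
    lapply(stats::setNames(MDS_DETRIMENTAL, MDS_DETRIMENTAL), function(g) {
      median_point(intake[[g]], med[[g]], beneficial = FALSE)
    }),
    list(alcohol = alcohol_point(intake$ethanol_g, window, points = 1L))
  )
  score_frame(intake, sub, "mds", threshold = 5L)
}

#' Tertile-based Mediterranean adherence score
#'
#' Scores eight components 0/1/2 by intake tertile -- vegetables, fruits+nuts,
#' legumes, fish, cereals and olive oil (the fat component) ascending, meat
#' and dairy descending -- plus a dichotomous alcohol component worth 2 points
#' inside the 5-25 g/day ethanol window. Totals run 0-18; >= 11 points is the
#' high-adherence group.
#'
#' @inheritParams score_mds
#' @return A tibble with `rmed_*` sub-scores, `rmed_points`, `rmed_group`
#'   and `rmed_reason`, as in [score_mds()].
#' @export
score_rmed <- function(intake, cutoffs = default_cutoffs(),
                       window = alcohol_window()) {
  comps <- c(RMED_BENEFICIAL, RMED_DETRIMENTAL)
  check_cutoffs(cutoffs, comps, "tertile")
  t1 <- cutoff_lookup(cutoffs, comps, "t1")
  t2 <- cutoff_lookup(cutoffs, comps, "t2")
  sub <- c(
    lapply(stats::setNames(RMED_BENEFICIAL, RMED_BENEFICIAL), function(g) {
      tertile_point(intake[[g]], t1[[g]], t2[[g]], beneficial = TRUE)
    }),
    lapply(stats::setNames(RMED_DETRIMENTAL, RMED_DETRIMENTAL), function(g) {
      tertile_point(intake[[g]], t1[[g]], t2[[g]], beneficial = FALSE)
    }),
    list(alcohol = alcohol_point(intake$ethanol_g, window, points = 2L))
  )
  score_frame(intake, sub, "rmed", threshold = 11L)
}

#' Seven-component pregnancy adherence score
#'
#' The pregnancy variant of the median-cutoff score: alcohol and the fat
#' ratio are dropped, and dairy is beneficial (calcium requirements rise in
#' pregnancy). Vegetables, fruits+nuts, legumes, fish, cereals and dairy
#' score 1 at or above their medians; meat scores 1 below its median. Totals
#' run 0-7; >= 4 points is the high-adherence group.
#'
#' @inheritParams score_mds
#' @return A tibble with `pmds_*` sub-scores, `pmds_points`, `pmds_group`
#'   and `pmds_reason`.
#' @export
score_pmds <- function(intake, cutoffs = default_cutoffs()) {
  comps <- c(PMDS_BENEFICIAL, PMDS_DETRIMENTAL)
  check_cutoffs(cutoffs, comps, "median")
  med <- cutoff_lookup(cutoffs, comps, "median")
  sub <- c(
    lapply(stats::setNames(PMDS_BENEFICIAL, PMDS_BENEFICIAL), function(g) {
      median_point(intake[[g]], med[[g]], beneficial = TRUE)
    }),
    list(meat = median_point(intake$meat, med[["meat"]], beneficial = FALSE))
  )
  score_frame(intake, sub, "pmds", threshold = 4L)
}

#' Compute all requested adherence scores
#'
#' @inheritParams score_mds
#' @param scores Which indices to compute; any of `"mds"`, `"rmed"`,
#'   `"pmds"`.
#' @return One tibble joining the per-score outputs on `participant_id`.
#' @export
score_diet <- function(intake, cutoffs = default_cutoffs(),
                       scores = c("mds", "rmed", "pmds"),
                       window = alcohol_window()) {
  scores <- match.arg(scores, several.ok = TRUE)
  parts <- list()
  if ("mds" %in% scores) parts <- c(parts, list(score_mds(intake, cutoffs, window)))
  if ("rmed" %in% scores) parts <- c(parts, list(score_rmed(intake, cutoffs, window)))
  if ("pmds" %in% scores) parts <- c(parts, list(score_pmds(intake, cutoffs)))
  purrr::reduce(parts, dplyr::left_join, by = "participant_id")
}

#' Derive within-sample cutoffs from observed intakes
#'
#' Computes per-component medians and/or tertile bounds from the observed
#' intake distribution (quantile type 7), for the sensitivity analysis that
#' replaces external reference cutoffs with the study sample's own. The fat
#' ratio is derived from `mufa_g`/`sfa_g`.
#'
#' @param intake Per-participant intake tibble as in [score_mds()].
#' @param scheme `"median"`, `"tertile"`, or `"both"` (default).
#' @return A cutoff tibble (`component`, `median`, `t1`, `t2`,
#'   `provenance = "within_sample"`). A constant component yields
#'   `t1 == t2` with a warning (all mass then lands in the third tertile
#'   under the lower-closed boundary rule).
#' @export
derive_cutoffs <- function(intake, scheme = c("both", "median", "tertile")) {
  scheme <- match.arg(scheme)
  values <- c(
    lapply(stats::setNames(MD_FOOD_GROUPS, MD_FOOD_GROUPS),
           function(g) intake[[g]]),
    list(fat_ratio = fat_ratio(intake$mufa_g, intake$sfa_g))
  )
  rows <- purrr::imap(values, function(x, nm) {
    x <- x[!is.na(x)]
    if (length(x) < 3) {
      abort(paste0("derive_cutoffs(): fewer than 3 observed values for ", nm))
    }
    t <- stats::quantile(x, c(1 / 3, 2 / 3), type = 7, names = FALSE)
    if (t[1] == t[2]) {
      warn(paste0("derive_cutoffs(): degenerate tertiles for constant-like component ", nm))
    }
    tibble::tibble(component = nm, median = stats::median(x),
                   t1 = t[1], t2 = t[2])
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(provenance = "within_sample")
  if (scheme == "median") out$t1 <- out$t2 <- NA_real_
  if (scheme == "tertile") out$median <- NA_real_
  out
}
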