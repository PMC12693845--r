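# Food-group components shared by the three adherence indices.
#
# mds:  9 components, 0/1 at the median -- beneficial: vegetables, fruits+nuts,
#       legumes, fish, cereals, MUFA/SFA ratio; detrimental: meat, dairy;
#       alcohol window 5-25 g/day ethanol.
# rmed: 9 components, 0/1/2 by tertile -- fat component is olive oil instead of
#       the MUFA/SFA ratio; alcohol window scored 0/2.
# pmds: 7 components, 0/1 at the median -- dairy beneficial, alcohol and the
#       fat ratio dropped.

MD_FOOD_GROUPS <- c(
  "vegetables", "fruits_nuts", "legumes", "fish", "cereals",
  "meat", "dairy", "olive_oil"
)

MDS_BENEFICIAL  <- c("vegetables", "fruits_nuts", "legumes", "fish", "cereals")
MDS_DETRIMENTAL <- c("meat", "dairy")
RMED_BENEFICIAL <- c(MDS_BENEFICIAL, "olive_oil")
RMED_DETRIMENTAL <- c("meat", "dairy")
PMDS_BENEFICIAL <- c(MDS_BENEFICIAL, "dairy")
PMDS_DETRIMENTAL <- "meat"

#' Alcohol window for the adherence indices
#'
#' Ethanol intakes inside this closed interval (g/day) score the alcohol
#' component: 1 point in the 9-component median-cutoff score, 2 points in the
#' tertile-based score.
#' @export
alcohol_window <- function() c(5, 25)

#' Illustrative reference cutoff table
#'
#' A synthetic stand-in for the external Mediterranean-population reference
#' cutoffs used by the adherence indices (the original reference values are
#' not published alongside the indices' definitions in a reusable form).
#' Medians drive the 0/1 components, tertile bounds drive the 0/1/2
#' components. All values are plausible g/day magnitudes for an adult diet
#' and are intended for examples and tests; analyses of real data should
#' supply their own table or derive one with [derive_cutoffs()].
#'
#' @return A tibble with columns `component`, `median`, `t1`, `t2` and
#'   `provenance` (here `"external_reference"`). The `fat_ratio` row is
#'   unitless (MUFA g / SFA g); all other rows are g/day.
#' @examples
#' default_cutoffs()
#' @export
default_cutoffs <- function() {
  tibble::tribble(
    ~component,    ~median, ~t1,    ~t2,
    "vegetables",  250,     200,    320,
    "fruits_nuts", 225,     170,    290,
    "legumes",     60,      45,     80,
    "fish",        80,      60,     105,
    "cereals",     300,     260,    350,
    "meat",        100,     80,     125,
    "dairy",       150,     110,    200,
    "olive_oil",   10,      5,      15,
    "fat_ratio",   1.3,     1.0,    1.7
  ) |>
    dplyr::mutate(provenance = "external_reference")
}

# validate a cutoff table covers the components a score needs
check_cutoffs <- function(cutoffs, components, need = c("median", "tertile")) {
  need <- match.arg(need)
  stopifnot(is.data.frame(cutoffs), all(c("component") %in% names(cutoffs)))
  missing_rows <- setdiff(components, cutoffs$component)
  if (length(missing_rows) > 0) {
    abort(paste0(
      "Cutoff table is missing component(s): ",
      paste(missing_rows, collapse = ", ")
    ))
  }
  cols <- if (need == "median") "median" else c("t1", "t2")
  if (!all(cols %in% names(cutoffs))) {
    abort(paste0("Cutoff table lacks required column(s): ",
                 paste(setdiff(cols, names(cutoffs)), collapse = ", ")))
  }
  sub <- cutoffs[cutoffs$component %in% components, ]
  if (need == "tertile" && any(sub$t1 > sub$t2, na.rm = TRUE)) {
    abort("Cutoff table has t1 > t2 for at least one component")
  }
  invisible(cutoffs)
}

cutoff_lookup <- function(cutoffs, components, col) {
  stats::setNames(cutoffs[[col]][match(components, cutoffs$component)], components)
}
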