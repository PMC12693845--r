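# FFQ arithmetic: item-level frequencies and portions -> daily food-group
# intakes, ethanol and energy.

#' Daily intake of a food item
#'
#' Estimated daily intake (g/day) is the reported intake frequency (times per
#' day) multiplied by the portion size (g). Vectorised.
#'
#' @param frequency_per_day Non-negative intake frequency per day.
#' @param portion_g Non-negative portion size in grams.
#' @return Numeric g/day, `frequency_per_day * portion_g`.
#' @examples
#' daily_intake(2, 50)   # 100 g/day
#' daily_intake(0.5, 120)
#' @export
daily_intake <- function(frequency_per_day, portion_g) {
  if (any(frequency_per_day < 0, na.rm = TRUE) || any(portion_g < 0, na.rm = TRUE)) {
    abort("frequency_per_day and portion_g must be non-negative")
  }
  frequency_per_day * portion_g
}

#' Total daily energy intake per participant
#'
#' Sums energy over a participant's FFQ items as
#' `daily_intake * energy_per_100g / 100` (energy density times amount).
#'
#' @param records A data frame of FFQ item records with columns
#'   `participant_id`, `frequency_per_day`, `portion_g`, `energy_per_100g`
#'   (kcal per 100 g).
#' @return A tibble with one row per participant: `participant_id`,
#'   `energy_kcal`, and `energy_missing` (TRUE when any item lacked an energy
#'   density; such participants get `NA` energy). Participants with no
#'   records are absent; an empty input returns an empty tibble with a
#'   warning.
#' @examples
#' recs <- tibble::tibble(
#'   participant_id = c(1, 1), frequency_per_day = c(1, 2),
#'   portion_g = c(100, 100), energy_per_100g = c(90, 50)
#' )
#' total_energy(recs) # 90 + 100 = 190 kcal/day
#' @export
total_energy <- function(records) {
  stopifnot(all(c("participant_id", "frequency_per_day", "portion_g",
                  "energy_per_100g") %in% names(records)))
  if (nrow(records) == 0) {
    warn("total_energy(): no FFQ records supplied; returning empty table")
    return(tibble::tibble(participant_id = character(0),
                          energy_kcal = numeric(0),
                          energy_missing = logical(0)))
  }
  records |>
    dplyr::mutate(
      item_kcal = daily_intake(.data$frequency_per_day, .data$portion_g) *
        .data$energy_per_100g / 100
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      energy_missing = anyNA(.data$energy_per_100g),
      energy_kcal = ifelse(.data$energy_missing[1], NA_real_,
                           sum(.data$item_kcal)),
      .groups = "drop"
    ) |>
    dplyr::relocate("energy_kcal", .after = "participant_id")
}

#' Aggregate FFQ items into scored food-group intakes
#'
#' Maps item-level daily intakes onto the food groups used by the adherence
#' indices and sums within groups. Items absent from the mapping are ignored
#' (with a message); groups with no mapped, observed item for a participant
#' are `NA` and flagged missing.
#'
#' @param records FFQ item records (`participant_id`, `item_id`,
#'   `frequency_per_day`, `portion_g`, optionally `energy_per_100g`).
#' @param mapping A two-column data frame (`item_id`, `group`) where `group`
#'   is one of the scored food groups (`r paste(MD_FOOD_GROUPS, collapse=", ")`),
#'   `mufa`, `sfa`, or `ethanol`.
#' @param energy If `TRUE` (default) and energy densities are present, a
#'   per-participant `energy_kcal` column is added via [total_energy()].
#' @return A wide tibble, one row per participant, with one g/day column per
#'   food group (`mufa`/`sfa`/`ethanol` become `mufa_g`/`sfa_g`/`ethanol_g`)
#'   and logical `missing_<group>` flags.
#' @export
aggregate_components <- function(records, mapping, energy = TRUE) {
  stopifnot(all(c("item_id", "group") %in% names(mapping)))
  known <- c(MD_FOOD_GROUPS, "mufa", "sfa", "ethanol")
  bad <- setdiff(unique(mapping$group), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown food group(s) in mapping: ", paste(bad, collapse = ", ")))
  }
  unmapped <- setdiff(unique(records$item_id), mapping$item_id)
  if (length(unmapped) > 0) {
    rlang::inform(paste0("Ignoring ", length(unmapped),
                         " unmapped FFQ item(s): ",
                         paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  long <- records |>
    dplyr::inner_join(mapping, by = "item_id") |>
    dplyr::mutate(grams = daily_intake(.data$frequency_per_day, .data$portion_g)) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop")

  wide <- long |>
    tidyr::pivot_wider(names_from = "group", values_from = "grams")
  for (g in known) {
    if (!g %in% names(wide)) wide[[g]] <- NA_real_
  }
  out <- wide |>
    dplyr::rename(mufa_g = "mufa", sfa_g = "sfa", ethanol_g = "ethanol") |>
    dplyr::relocate(dplyr::all_of(MD_FOOD_GROUPS), .after = "participant_id")
  value_cols <- setdiff(names(out), "participant_id")
  for (g in value_cols) {
    out[[paste0("missing_", g)]] <- is.na(out[[g]])
  }
  if (energy && "energy_per_100g" %in% names(records)) {
    out <- dplyr::left_join(out, total_energy(records), by = "participant_id")
  }
  out
}

#' MUFA/SFA fat ratio
#'
#' The fat-quality component of the 9-component median-cutoff score. Undefined
#' (NA) when saturated fat is zero or missing.
#' @param mufa_g,sfa_g Monounsaturated and saturated fat intake, g/day.
#' @return Numeric ratio; `NA` where `sfa_g` is 0 or missing.
#' @export
fat_ratio <- function(mufa_g, sfa_g) {
  ifelse(is.na(sfa_g) | sfa_g <= 0, NA_real_, mufa_g / sfa_g)
}
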