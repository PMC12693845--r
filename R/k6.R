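# Kessler-6 psychological distress scale: six items scored 0-4, total 0-24,
# distress defined as total >= 13.

K6_BREAKS <- c(-Inf, 4, 9, 12, Inf)
K6_LEVELS <- c("le4", "5to9", "10to12", "ge13")

#' Score the Kessler-6 psychological distress scale
#'
#' Sums six item responses (each an integer 0-4) into a 0-24 total, assigns
#' the reporting category (<=4, 5-9, 10-12, >=13), and flags psychological
#' distress at the standard total >= 13 cutoff. No prorating: a participant
#' with any missing item gets a missing total, category and distress flag,
#' with a reason code.
#'
#' @param items A data frame or matrix of six item columns, or a tibble with
#'   a `participant_id` column plus six item columns (columns matching
#'   `item_cols`).
#' @param item_cols Names of the six item columns; defaults to
#'   `k6_1` .. `k6_6` if present, otherwise the six non-id columns.
#' @return A tibble with `participant_id` (when supplied), `k6_total`,
#'   `k6_category` (factor le4/5to9/10to12/ge13), `distress` (logical,
#'   total >= 13) and `k6_reason`.
#' @examples
#' score_k6(tibble::tibble(
#'   k6_1 = c(3, 2), k6_2 = 2, k6_3 = 2, k6_4 = 2, k6_5 = 2, k6_6 = 2
#' )) # totals 13 (distress) and 12 (no distress)
#' @export
score_k6 <- function(items, item_cols = NULL) {
  items <- tibble::as_tibble(items)
  id <- if ("participant_id" %in% names(items)) items$participant_id else NULL
  if (is.null(item_cols)) {
    item_cols <- if (all(paste0("k6_", 1:6) %in% names(items))) {
      paste0("k6_", 1:6)
    } else {
      setdiff(names(items), "participant_id")
    }
  }
  if (length(item_cols) != 6) {
    abort("score_k6(): exactly six item columns are required")
  }
  m <- as.matrix(items[item_cols])
  storage.mode(m) <- "double"
  ok <- !is.na(m)
  bad <- ok & (m < 0 | m > 4 | m != round(m))
  if (any(bad)) {
    abort("score_k6(): item responses must be integers in 0..4")
  }
  n_miss <- rowSums(!ok)
  total <- ifelse(n_miss > 0, NA_real_, rowSums(m))
  category <- cut(total, K6_BREAKS, labels = K6_LEVELS)
  out <- tibble::tibble(
    k6_total = as.integer(total),
    k6_category = category,
    distress = total >= 13,
    k6_reason = ifelse(n_miss > 0, "missing_k6_item", NA_character_)
  )
  if (!is.null(id)) out <- dplyr::bind_cols(tibble::tibble(participant_id = id), out)
  out
}
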