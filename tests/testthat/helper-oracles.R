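# Independent brute-force re-computations used as oracles. These walk each
# participant and component one at a time with explicit if/else logic, on
# purpose sharing no code with the vectorised implementations.

cutoffs_as_list <- function(cutoffs) {
  lapply(stats::setNames(cutoffs$component, cutoffs$component), function(cp) {
    row <- cutoffs[cutoffs$component == cp, ]
    list(median = row$median, t1 = row$t1, t2 = row$t2)
  })
}

oracle_mds_one <- function(row, cl) {
  pts <- 0L
  for (cp in c("vegetables", "fruits_nuts", "legumes", "fish", "cereals")) {
    if (is.na(row[[cp]])) return(NA_integer_)
    if (row[[cp]] >= cl[[cp]]$median) pts <- pts + 1L
  }
  if (is.na(row$sfa_g) || row$sfa_g <= 0 || is.na(row$mufa_g)) return(NA_integer_)
  if (row$mufa_g / row$sfa_g >= cl$fat_ratio$median) pts <- pts + 1L
  for (cp in c("dairy", "meat")) {
    if (is.na(row[[cp]])) return(NA_integer_)
    if (row[[cp]] < cl[[cp]]$median) pts <- pts + 1L
  }
  if (is.na(row$ethanol_g)) return(NA_integer_)
  if (row$ethanol_g >= 5 && row$ethanol_g <= 25) pts <- pts + 1L
  pts
}

oracle_rmed_one <- function(row, cl) {
  tert <- function(x, t1, t2) {
    if (x < t1) 0L else if (x < t2) 1L else 2L
  }
  pts <- 0L
  for (cp in c("vegetables", "fruits_nuts", "legumes", "fish", "cereals",
               "olive_oil")) {
    if (is.na(row[[cp]])) return(NA_integer_)
    pts <- pts + tert(row[[cp]], cl[[cp]]$t1, cl[[cp]]$t2)
  }
  for (cp in c("meat", "dairy")) {
    if (is.na(row[[cp]])) return(NA_integer_)
    pts <- pts + (2L - tert(row[[cp]], cl[[cp]]$t1, cl[[cp]]$t2))
  }
  if (is.na(row$ethanol_g)) return(NA_integer_)
  if (row$ethanol_g >= 5 && row$ethanol_g <= 25) pts <- pts + 2L
  pts
}

oracle_pmds_one <- function(row, cl) {
  pts <- 0L
  for (cp in c("vegetables", "fruits_nuts", "legumes", "fish", "cereals",
               "dairy")) {
    if (is.na(row[[cp]])) return(NA_integer_)
    if (row[[cp]] >= cl[[cp]]$median) pts <- pts + 1L
  }
  if (is.na(row$meat)) return(NA_integer_)
  if (row$meat < cl$meat$median) pts <- pts + 1L
  pts
}

oracle_scores <- function(intake, cutoffs) {
  cl <- cutoffs_as_list(cutoffs)
  n <- nrow(intake)
  out <- data.frame(mds = integer(n), rmed = integer(n), pmds = integer(n))
  for (i in seq_len(n)) {
    row <- as.list(intake[i, ])
    out$mds[i] <- oracle_mds_one(row, cl)
    out$rmed[i] <- oracle_rmed_one(row, cl)
    out$pmds[i] <- oracle_pmds_one(row, cl)
  }
  out
}

oracle_k6_one <- function(items) {
  total <- 0L
  for (v in items) {
    if (is.na(v)) return(list(total = NA_integer_, category = NA, distress = NA))
    total <- total + v
  }
  category <- if (total <= 4) "le4" else if (total <= 9) "5to9" else
    if (total <= 12) "10to12" else "ge13"
  list(total = total, category = category, distress = total >= 13)
}

# random intake vectors spanning the default cutoffs (including values at
# and around the boundaries)
random_intakes <- function(n, seed = 1) {
  set.seed(seed)
  cuts <- default_cutoffs()
  med <- stats::setNames(cuts$median, cuts$component)
  draw <- function(cp) {
    base <- med[[cp]] * stats::runif(n, 0, 2.2)
    at_bound <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9))
    row <- cuts[cuts$component == cp, ]
    base[at_bound] <- sample(c(row$median, row$t1, row$t2),
                             sum(at_bound), replace = TRUE)
    base
  }
  tibble::tibble(
    participant_id = sprintf("R%04d", seq_len(n)),
    vegetables = draw("vegetables"), fruits_nuts = draw("fruits_nuts"),
    legumes = draw("legumes"), fish = draw("fish"), cereals = draw("cereals"),
    meat = draw("meat"), dairy = draw("dairy"), olive_oil = draw("olive_oil"),
    mufa_g = stats::runif(n, 5, 45), sfa_g = stats::runif(n, 5, 35),
    ethanol_g = sample(c(0, 4.999, 5, 10, 25, 25.001, 40), n, replace = TRUE)
  )
}

# a single intake row, all fields controllable
intake_row <- function(...) {
  base <- tibble::tibble(
    participant_id = "X", vegetables = 250, fruits_nuts = 225, legumes = 60,
    fish = 80, cereals = 300, meat = 99, dairy = 149, olive_oil = 10,
    mufa_g = 30, sfa_g = 20, ethanol_g = 10
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}
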