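cuts <- default_cutoffs()

test_that("maximal and minimal adherence hit the score range endpoints", {
  med <- stats::setNames(cuts$median, cuts$component)
  best <- intake_row(
    vegetables = med["vegetables"], fruits_nuts = med["fruits_nuts"],
    legumes = med["legumes"], fish = med["fish"], cereals = med["cereals"],
    meat = med["meat"] - 1, dairy = med["dairy"] - 1,
    mufa_g = med["fat_ratio"] * 20, sfa_g = 20, ethanol_g = 10
  )
  s <- score_mds(best, cuts)
  expect_equal(s$mds_points, 9L)          # boundary: at-median counts
  expect_equal(as.character(s$mds_group), "high")

  worst <- intake_row(
    vegetables = med["vegetables"] - 1, fruits_nuts = med["fruits_nuts"] - 1,
    legumes = med["legumes"] - 1, fish = med["fish"] - 1,
    cereals = med["cereals"] - 1, meat = med["meat"], dairy = med["dairy"],
    mufa_g = 1, sfa_g = 20, ethanol_g = 0
  )
  s0 <- score_mds(worst, cuts)
  expect_equal(s0$mds_points, 0L)
  expect_equal(as.character(s0$mds_group), "low")

  t2 <- stats::setNames(cuts$t2, cuts$component)
  t1 <- stats::setNames(cuts$t1, cuts$component)
  r_best <- intake_row(
    vegetables = t2["vegetables"], fruits_nuts = t2["fruits_nuts"],
    legumes = t2["legumes"], fish = t2["fish"], cereals = t2["cereals"],
    olive_oil = t2["olive_oil"], meat = t1["meat"] - 1, dairy = t1["dairy"] - 1,
    ethanol_g = 10
  )
  r <- score_rmed(r_best, cuts)
  expect_equal(r$rmed_points, 18L)
  expect_equal(as.character(r$rmed_group), "high")

  p_best <- intake_row(dairy = med["dairy"], meat = med["meat"] - 1)
  p <- score_pmds(p_best, cuts)
  expect_equal(p$pmds_points, 7L)
  expect_equal(as.character(p$pmds_group), "high")
})

test_that("group thresholds split exactly at 5, 11 and 4 points", {
  # engineer exact point totals component by component
  med <- stats::setNames(cuts$median, cuts$component)
  mk <- function(n_beneficial) {
    groups <- c("vegetables", "fruits_nuts", "legumes", "fish", "cereals")
    args <- list(meat = med["meat"], dairy = med["dairy"], mufa_g = 1,
                 sfa_g = 20, ethanol_g = 0)  # all non-food components score 0
    for (i in seq_along(groups)) {
      args[[groups[i]]] <- med[groups[i]] + if (i <= n_beneficial) 0 else -1
    }
    do.call(intake_row, args)
  }
  s4 <- score_mds(mk(4), cuts); s5 <- score_mds(mk(5), cuts)
  expect_equal(s4$mds_points, 4L); expect_equal(as.character(s4$mds_group), "low")
  expect_equal(s5$mds_points, 5L); expect_equal(as.character(s5$mds_group), "high")

  t1 <- stats::setNames(cuts$t1, cuts$component)
  t2 <- stats::setNames(cuts$t2, cuts$component)
  mk_r <- function(pts_from_five) {
    # five beneficial components supply 0/1/2 each; rest pinned to 0
    groups <- c("vegetables", "fruits_nuts", "legumes", "fish", "cereals")
    args <- list(olive_oil = 0, meat = t2["meat"], dairy = t2["dairy"],
                 ethanol_g = 0)
    per <- c(rep(2, pts_from_five %/% 2), rep(1, pts_from_five %% 2))
    per <- c(per, rep(0, 5 - length(per)))
    for (i in seq_along(groups)) {
      row <- cuts[cuts$component == groups[i], ]
      args[[groups[i]]] <- c(0, row$t1, row$t2)[per[i] + 1]
    }
    do.call(intake_row, args)
  }
  r10 <- score_rmed(mk_r(10), cuts); r11 <- score_rmed(mk_r(9), cuts)
  expect_equal(r10$rmed_points, 10L)
  expect_equal(as.character(r10$rmed_group), "low")
  # 9 from the five groups + 2 more via alcohol window
  r11b <- score_rmed(dplyr::mutate(mk_r(9), ethanol_g = 5), cuts)
  expect_equal(r11b$rmed_points, 11L)
  expect_equal(as.character(r11b$rmed_group), "high")

  mk_p <- function(n_beneficial) {
    groups <- c("vegetables", "fruits_nuts", "legumes", "fish", "cereals",
                "dairy")
    args <- list(meat = med["meat"])   # meat at median scores 0
    for (i in seq_along(groups)) {
      args[[groups[i]]] <- med[groups[i]] + if (i <= n_beneficial) 0 else -1
    }
    do.call(intake_row, args)
  }
  p3 <- score_pmds(mk_p(3), cuts); p4 <- score_pmds(mk_p(4), cuts)
  expect_equal(p3$pmds_points, 3L); expect_equal(as.character(p3$pmds_group), "low")
  expect_equal(p4$pmds_points, 4L); expect_equal(as.character(p4$pmds_group), "high")
})

test_that("tertile boundaries are lower-closed and alcohol window closed", {
  row <- cuts[cuts$component == "vegetables", ]
  probe <- function(v) {
    score_rmed(intake_row(vegetables = v, fruits_nuts = 0, legumes = 0,
                          fish = 0, cereals = 0, olive_oil = 0,
                          meat = row$t2 * 10, dairy = 1e6, ethanol_g = 0),
               cuts)$rmed_points
  }
  expect_equal(probe(row$t1 - 1e-9), 0L)
  expect_equal(probe(row$t1), 1L)          # exactly at t1 -> second tertile
  expect_equal(probe(row$t2), 2L)

  eth <- function(e) score_mds(intake_row(ethanol_g = e), cuts)$mds_alcohol
  expect_equal(eth(4.999), 0L)
  expect_equal(eth(5), 1L)
  expect_equal(eth(25), 1L)
  expect_equal(eth(25.001), 0L)
})

test_that("dairy flips sign between the 9-component and pregnancy scores", {
  med <- stats::setNames(cuts$median, cuts$component)
  high_dairy <- intake_row(dairy = med["dairy"] + 50)
  expect_equal(score_mds(high_dairy, cuts)$mds_dairy, 0L)
  expect_equal(score_pmds(high_dairy, cuts)$pmds_dairy, 1L)
  low_dairy <- intake_row(dairy = med["dairy"] - 50)
  expect_equal(score_mds(low_dairy, cuts)$mds_dairy, 1L)
  expect_equal(score_pmds(low_dairy, cuts)$pmds_dairy, 0L)
})

test_that("missing components produce reason-coded missing scores", {
  s <- score_mds(intake_row(fish = NA), cuts)
  expect_true(is.na(s$mds_points))
  expect_true(is.na(s$mds_group))
  expect_equal(s$mds_reason, "missing_fish")

  s2 <- score_mds(intake_row(sfa_g = 0), cuts)
  expect_true(is.na(s2$mds_points))
  expect_equal(s2$mds_reason, "missing_fat_ratio")

  # pregnancy score unaffected by missing ethanol or fat components
  p <- score_pmds(intake_row(sfa_g = 0, ethanol_g = NA), cuts)
  expect_false(is.na(p$pmds_points))
})

test_that("scores match the brute-force oracle on random intakes", {
  intake <- random_intakes(400, seed = 11)
  got <- score_diet(intake, cuts)
  want <- oracle_scores(intake, cuts)
  expect_equal(got$mds_points, want$mds)
  expect_equal(got$rmed_points, want$rmed)
  expect_equal(got$pmds_points, want$pmds)
  expect_true(all(got$mds_points >= 0 & got$mds_points <= 9))
  expect_true(all(got$rmed_points >= 0 & got$rmed_points <= 18))
  expect_true(all(got$pmds_points >= 0 & got$pmds_points <= 7))
})

test_that("scores are monotone in beneficial and detrimental intakes", {
  intake <- random_intakes(120, seed = 5)
  base <- score_diet(intake, cuts)
  for (cp in c("vegetables", "fruits_nuts", "legumes", "fish", "cereals")) {
    up <- intake
    up[[cp]] <- up[[cp]] * 1.5 + 10
    bumped <- score_diet(up, cuts)
    expect_true(all(bumped$mds_points >= base$mds_points))
    expect_true(all(bumped$rmed_points >= base$rmed_points))
    expect_true(all(bumped$pmds_points >= base$pmds_points))
  }
  up <- intake; up$meat <- up$meat * 1.5 + 10
  bumped <- score_diet(up, cuts)
  expect_true(all(bumped$mds_points <= base$mds_points))
  expect_true(all(bumped$rmed_points <= base$rmed_points))
  expect_true(all(bumped$pmds_points <= base$pmds_points))
  up <- intake; up$dairy <- up$dairy * 1.5 + 10
  bumped <- score_diet(up, cuts)
  expect_true(all(bumped$mds_points <= base$mds_points))
  expect_true(all(bumped$rmed_points <= base$rmed_points))
  expect_true(all(bumped$pmds_points >= base$pmds_points))
})

test_that("within-sample cutoffs reproduce order statistics", {
  intake <- intake_row()[rep(1, 9), ]
  intake$participant_id <- as.character(1:9)
  intake$vegetables <- as.numeric(1:9)
  cc <- suppressWarnings(derive_cutoffs(intake))  # other columns constant here
  veg <- cc[cc$component == "vegetables", ]
  expect_equal(veg$median, 5)
  expect_equal(c(veg$t1, veg$t2),
               unname(stats::quantile(1:9, c(1 / 3, 2 / 3), type = 7)))
  expect_equal(cc$provenance[1], "within_sample")

  tiny <- intake[1:3, ]
  tiny$vegetables <- c(1, 2, 3)
  expect_equal(suppressWarnings(derive_cutoffs(tiny))[1, ]$median, 2)

  const <- intake
  const$vegetables <- 100
  w <- capture_warnings(cc2 <- derive_cutoffs(const))
  expect_true(any(grepl("degenerate", w)))
  vrow <- cc2[cc2$component == "vegetables", ]
  expect_equal(vrow$t1, vrow$t2)
  # under the lower-closed rule all mass lands in the third tertile
  expect_equal(tertile_point <- score_rmed(
    intake_row(vegetables = 100, fruits_nuts = 0, legumes = 0, fish = 0,
               cereals = 0, olive_oil = 0, meat = 1e6, dairy = 1e6,
               ethanol_g = 0), cc2)$rmed_vegetables, 2L)

  expect_error(suppressWarnings(derive_cutoffs(tiny[1:2, ])), "fewer than 3")
})

test_that("pregnancy score relates to the 9-component score by construction", {
  # ethanol outside the window and fat ratio below median: the two scores
  # then differ only in the dairy component flip
  intake <- random_intakes(150, seed = 9)
  intake$ethanol_g <- 0
  intake$mufa_g <- 1
  s <- score_diet(intake, cuts)
  dairy_flip <- s$mds_dairy - s$pmds_dairy   # +1 or -1 or 0/0 impossible here
  expect_equal(s$mds_points - s$pmds_points, dairy_flip)
})
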