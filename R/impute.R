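# Single k-nearest-neighbour imputation of missing categorical covariates.

#' Impute missing categorical covariates by k-nearest neighbours
#'
#' Each missing cell of the named covariate columns is replaced by the modal
#' value among its k nearest donor rows, where distance is the Hamming count
#' of mismatching covariate values over the other columns (pairs where
#' either value is missing contribute half a mismatch, so rows with more
#' shared observed information rank closer). Exposure and outcome columns
#' are never imputed: only `columns` are touched, and observed cells are
#' never altered. Deterministic given `seed`: distance ties are broken by a
#' seeded row permutation and modal-vote ties by factor level order.
#'
#' At cohort scale the donor search is capped at `max_donors` complete rows
#' (seeded subsample), keeping the cost O(n_missing x max_donors) while
#' leaving imputed-level frequencies essentially unchanged.
#'
#' @param table A data frame.
#' @param columns Covariate columns (factor or character) to impute.
#' @param k Number of neighbours (default 5).
#' @param seed Integer seed for tie-breaking and donor subsampling.
#' @param max_donors Donor-pool cap, default 5000.
#' @return A list with `table` (completed) and `audit`, a tibble listing
#'   every imputed cell (`row`, `column`, `value`).
#' @export
impute_knn <- function(table, columns, k = 5L, seed = 1L, max_donors = 5000L) {
  stopifnot(k >= 1)
  bad <- setdiff(columns, names(table))
  if (length(bad) > 0) {
    abort(paste0("Unknown column(s): ", paste(bad, collapse = ", ")))
  }
  audit <- list()
  any_missing <- purrr::map_lgl(columns, ~ anyNA(table[[.x]]))
  if (!any(any_missing)) {
    return(list(table = table, audit = tibble::tibble(
      row = integer(0), column = character(0), value = character(0))))
  }

  # integer-code the covariate columns once; NA stays NA
  codes <- purrr::map(columns, function(col) {
    f <- table[[col]]
    if (!is.factor(f)) f <- factor(f)
    list(code = as.integer(f), levels = levels(f))
  })
  names(codes) <- columns
  code_mat <- do.call(cbind, purrr::map(codes, "code"))

  all_missing_features <- rowSums(!is.na(code_mat)) == 0
  if (any(all_missing_features & rowSums(is.na(code_mat)) > 0)) {
    abort("impute_knn(): some rows are missing every distance feature")
  }

  set.seed(seed)
  tie_noise <- stats::runif(nrow(table))   # seeded distance tie-break

  for (j in seq_along(columns)) {
    col <- columns[j]
    target <- code_mat[, j]
    miss_rows <- which(is.na(target))
    if (length(miss_rows) == 0) next
    donor_rows <- which(!is.na(target))
    if (length(donor_rows) < k) {
      abort(paste0("impute_knn(): fewer than k donors for column ", col))
    }
    if (length(donor_rows) > max_donors) {
      donor_rows <- sort(sample(donor_rows, max_donors))
    }
    feat <- code_mat[, -j, drop = FALSE]
    dm <- matrix(0, length(miss_rows), length(donor_rows))
    for (f in seq_len(ncol(feat))) {
      a <- feat[miss_rows, f]
      b <- feat[donor_rows, f]
      mism <- outer(a, b, `!=`)                 # NA where either side is NA
      mism[is.na(mism)] <- 0.5
      dm <- dm + mism
    }
    lev <- codes[[col]]$levels
    imputed <- vapply(seq_along(miss_rows), function(i) {
      ord <- order(dm[i, ], tie_noise[donor_rows])
      votes <- target[donor_rows[ord[seq_len(k)]]]
      tab <- tabulate(votes, nbins = length(lev))
      which.max(tab)                             # first-seen level wins ties
    }, integer(1))
    code_mat[miss_rows, j] <- imputed
    audit[[length(audit) + 1]] <- tibble::tibble(
      row = miss_rows, column = col, value = lev[imputed])
  }

  for (j in seq_along(columns)) {
    col <- columns[j]
    lev <- codes[[col]]$levels
    filled <- lev[code_mat[, j]]
    table[[col]] <- if (is.factor(table[[col]])) {
      factor(filled, levels = levels(table[[col]]))
    } else filled
  }
  list(table = table,
       audit = if (length(audit)) dplyr::bind_rows(audit) else
         tibble::tibble(row = integer(0), column = character(0),
                        value = character(0)))
}
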