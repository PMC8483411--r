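# pIC50 three-class activity labeling and dataset preparation.
#
# Class boundaries (closed/open exactly as published): inactive pIC50 < 5,
# weak 5 <= pIC50 < 6, potent pIC50 >= 6. Most public kinase bioactivity
# mass sits near pIC50 5, which is what motivated classification over
# regression in the method this scheme comes from.

ACTIVITY_LEVELS <- c("inactive", "weak", "potent")

#' Classify pIC50 values into activity classes
#'
#' @param pic50 numeric vector of -log10(IC50 in molar).
#' @return factor with levels `inactive`, `weak`, `potent`.
#' @examples
#' pic50_class(c(4.999, 5, 5.5, 6))  # inactive weak weak potent
#' @export
pic50_class <- function(pic50) {
  if (any(!is.finite(pic50)))
    stop("pic50 values must be finite", call. = FALSE)
  cut(pic50, breaks = c(-Inf, 5, 6, Inf), labels = ACTIVITY_LEVELS,
      right = FALSE)
}

#' Class distribution of activity records
#'
#' @param records data frame with a `pic50` column (or a numeric vector).
#' @param breaks histogram breaks passed to [graphics::hist()] machinery
#'   (computed, not plotted).
#' @return list with `counts` (named, one per class), `n`, and `histogram`
#'   (data frame of bin mids/counts summarising the pIC50 distribution).
#' @export
class_distribution <- function(records, breaks = "Sturges") {
  pic50 <- if (is.data.frame(records)) records$pic50 else as.numeric(records)
  if (length(pic50) == 0) {
    counts <- stats::setNames(rep(0L, 3), ACTIVITY_LEVELS)
    return(list(counts = counts, n = 0L,
                histogram = data.frame(mid = numeric(), count = integer())))
  }
  cls <- pic50_class(pic50)
  counts <- table(cls)
  h <- graphics::hist(pic50, breaks = breaks, plot = FALSE)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n = length(pic50),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Hold-out split of activity records
#'
#' Deterministic for a fixed seed; partitions are disjoint and exhaustive.
#' `stratify = TRUE` samples the test fraction within each activity class;
#' `group_by_compound = TRUE` keeps all records of a compound on the same
#' side (the split is then over compounds, and the test fraction is
#' approximate in records).
#'
#' @param records data frame with columns `compound`, `target`, `pic50`.
#' @param test_fraction fraction of records (or compounds) held out,
#'   in (0, 1).
#' @param seed integer RNG seed.
#' @param stratify stratify by activity class.
#' @param group_by_compound compound-disjoint split.
#' @return list with `train` and `test` data frames.
#' @export
holdout_split <- function(records, test_fraction = 0.1, seed = 1,
                          stratify = FALSE, group_by_compound = FALSE) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  rng <- local_rng(seed)
  on.exit(rng())
  if (group_by_compound) {
    comps <- unique(records$compound)
    n_test <- max(1L, round(length(comps) * test_fraction))
    test_comps <- sample(comps, n_test)
    test_idx <- records$compound %in% test_comps
  } else if (stratify) {
    cls <- pic50_class(records$pic50)
    test_idx <- logical(nrow(records))
    for (lv in levels(cls)) {
      rows <- which(cls == lv)
      if (length(rows) == 0) next
      n_test <- round(length(rows) * test_fraction)
      if (n_test > 0) test_idx[sample(rows, n_test)] <- TRUE
    }
  } else {
    n_test <- max(1L, round(nrow(records) * test_fraction))
    test_idx <- logical(nrow(records))
    test_idx[sample(nrow(records), n_test)] <- TRUE
  }
  list(train = records[!test_idx, , drop = FALSE],
       test = records[test_idx, , drop = FALSE])
}

# Seed-scoped RNG: sets the seed, returns a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
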