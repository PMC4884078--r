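## Cross-category generalisation decoding. A linear SVM is trained to
## separate two odors from two different categories and tested on the
## complementary odor pair of the same categories, so above-chance
## accuracy requires category-level information that generalises across
## odor identity. With three categories of two exemplars there are twelve
## train/test assignments; accuracies are averaged over all of them.

#' Enumerate cross-category decoding folds
#'
#' For every unordered pair of categories and every assignment of one odor
#' per category to the training role, a fold trains on that odor pair and
#' tests on the two withheld exemplars of the same categories: 3 category
#' pairs x 4 assignments = 12 folds for the default 3 x 2 design.
#'
#' @param odors odor labels
#' @param categories named odor -> category map
#' @return data.frame of class `DecodingFoldSpec`: fold, train_i, train_j,
#'   test_i, test_j, category_i, category_j
#' @export
makeCrossCategoryFolds <- function(odors = .defaultOdors,
                                   categories = .defaultCategories) {
  cats <- unique(unname(categories[odors]))
  by_cat <- split(odors, unname(categories[odors]))[cats]
  bad <- names(by_cat)[lengths(by_cat) != 2L]
  if (length(bad)) {
    stop("cross-category folds need exactly two exemplars per category; ",
         "offending categories: ", paste(bad, collapse = ", "))
  }
  cat_pairs <- utils::combn(cats, 2L)
  folds <- list()
  for (p in seq_len(ncol(cat_pairs))) {
    ci <- cat_pairs[1L, p]; cj <- cat_pairs[2L, p]
    for (a in 1:2) for (b in 1:2) {
      folds <- c(folds, list(data.frame(
        train_i = by_cat[[ci]][a], train_j = by_cat[[cj]][b],
        test_i = by_cat[[ci]][3L - a], test_j = by_cat[[cj]][3L - b],
        category_i = ci, category_j = cj, stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, folds)
  out <- cbind(fold = seq_len(nrow(out)), out)
  class(out) <- c("DecodingFoldSpec", class(out))
  out
}

#' Cross-category SVM decoding for one pattern set
#'
#' Per fold: fit a linear SVM (cost = 1, no internal rescaling) on the
#' training odor pair's patterns from all runs, labelled by category, and
#' classify the withheld complementary pair; accuracy is the fraction of
#' correctly classified test patterns. Folds whose training patterns are
#' all identical are skipped (logged) and the subject accuracy is the mean
#' over the remaining folds.
#'
#' @param patterns a [BetaPatternSet-class]
#' @param folds a [makeCrossCategoryFolds()] table (default: folds derived
#'   from the pattern set's own category map)
#' @return list of class `DecodingResult`: `accuracy` (mean over folds),
#'   `fold_accuracy`, `skipped` fold ids, `chance` (0.5)
#' @export
decodeCategory <- function(patterns, folds = NULL) {
  info <- patternInfo(patterns)
  X <- t(betaMatrix(patterns))             # patterns x voxels
  if (is.null(folds)) {
    odors <- unique(info$odor)
    cats <- info$category[match(odors, info$odor)]
    names(cats) <- odors
    folds <- makeCrossCategoryFolds(odors, cats)
  }
  fold_acc <- rep(NA_real_, nrow(folds))
  skipped <- integer(0L)
  for (f in seq_len(nrow(folds))) {
    tr_idx <- info$odor %in% c(folds$train_i[f], folds$train_j[f])
    te_idx <- info$odor %in% c(folds$test_i[f], folds$test_j[f])
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- factor(info$category[tr_idx],
                  levels = c(folds$category_i[f], folds$category_j[f]))
    if (nrow(unique(Xtr)) == 1L) {
      skipped <- c(skipped, f)
      next
    }
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1,
                      scale = FALSE)
    pred <- stats::predict(fit, X[te_idx, , drop = FALSE])
    truth <- factor(info$category[te_idx], levels = levels(ytr))
    fold_acc[f] <- mean(pred == truth)
  }
  if (length(skipped)) {
    message("skipped ", length(skipped),
            " degenerate fold(s): identical training patterns")
  }
  ## with no informative fold at all, the classifier can only guess:
  ## report chance
  acc <- if (all(is.na(fold_acc))) 0.5 else mean(fold_acc, na.rm = TRUE)
  structure(list(accuracy = acc,
                 fold_accuracy = fold_acc, skipped = skipped,
                 chance = 0.5),
            class = "DecodingResult")
}

#' Group-level test of decoding accuracy against chance
#'
#' One-tailed one-sample t test of per-subject mean accuracies against the
#' chance level, the standard screen for category-coding regions.
#'
#' @param accuracies per-subject mean accuracies
#' @param chance chance level (default 0.5)
#' @return list: `t`, `df`, `p` (one-tailed, mean > chance),
#'   `mean_accuracy`
#' @export
groupDecodingTest <- function(accuracies, chance = 0.5) {
  if (length(accuracies) < 3L) stop("need at least three subjects")
  res <- tTest(accuracies, mu = chance, tail = "greater")
  list(t = res$t, df = res$df, p = res$p,
       mean_accuracy = mean(accuracies))
}
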