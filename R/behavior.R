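## Behavioural categorisation measures: descriptor and similarity indices,
## hierarchical clustering of similarity ratings, triangle-test (3-AFC)
## scoring and catch-trial performance.

#' Categorisation indices from a ratings bundle
#'
#' Descriptor index = mean rating of the matching-category descriptor minus
#' mean rating of non-matching descriptors. Similarity index = mean
#' within-category pair similarity minus mean across-category pair
#' similarity. Both are within-minus-across contrasts on the 0-10 scale.
#'
#' @param bundle a [generateRatings()] bundle, or any list with
#'   `descriptor` (odor, descriptor, rating), `similarity` (odor_i,
#'   odor_j, within_category, rating) and `categories`
#' @return one-row data.frame of class `CategorizationIndex`:
#'   descriptor_index, similarity_index
#' @export
categorizationIndices <- function(bundle) {
  d <- bundle$descriptor
  cats <- bundle$categories
  need <- expand.grid(odor = names(cats), descriptor = unique(unname(cats)),
                      stringsAsFactors = FALSE)
  have <- paste(d$odor, d$descriptor)
  gaps <- setdiff(paste(need$odor, need$descriptor), have)
  if (length(gaps)) {
    stop("missing descriptor rating(s): ", paste(gaps, collapse = "; "))
  }
  match_cat <- unname(cats[d$odor]) == d$descriptor
  descriptor_index <- mean(d$rating[match_cat]) - mean(d$rating[!match_cat])
  s <- bundle$similarity
  n_odors <- length(cats)
  if (nrow(s) != choose(n_odors, 2L) || anyNA(s$rating)) {
    stop("missing similarity rating(s): expected all ",
         choose(n_odors, 2L), " odor pairs")
  }
  similarity_index <- mean(s$rating[s$within_category]) -
    mean(s$rating[!s$within_category])
  out <- data.frame(descriptor_index = descriptor_index,
                    similarity_index = similarity_index)
  class(out) <- c("CategorizationIndex", class(out))
  out
}

#' Hierarchical clustering of mean pairwise similarity
#'
#' Converts the symmetric odor similarity matrix to a dissimilarity
#' (scale maximum minus similarity), runs agglomerative clustering
#' (average linkage by default) and cuts at three clusters — the analysis
#' that asks whether subjects sort the six odors into their three
#' categories.
#'
#' @param similarity symmetric odor x odor similarity matrix (dimnames =
#'   odor labels) or a pair-table as in a ratings bundle
#' @param scale_max similarity scale maximum (default 10)
#' @param linkage `"average"` (default), `"single"` or `"complete"`
#' @param k number of clusters to cut (default 3)
#' @return list: `partition` (named cluster memberships), `merge_heights`,
#'   `hclust` (the tree)
#' @export
clusterSimilarity <- function(similarity, scale_max = 10,
                              linkage = c("average", "single", "complete"),
                              k = 3L) {
  linkage <- match.arg(linkage)
  if (is.data.frame(similarity)) {
    odors <- sort(unique(c(similarity$odor_i, similarity$odor_j)))
    M <- matrix(NA_real_, length(odors), length(odors),
                dimnames = list(odors, odors))
    for (r in seq_len(nrow(similarity))) {
      M[similarity$odor_i[r], similarity$odor_j[r]] <- similarity$rating[r]
      M[similarity$odor_j[r], similarity$odor_i[r]] <- similarity$rating[r]
    }
    diag(M) <- scale_max
    similarity <- M
  }
  if (!isSymmetric(unname(similarity))) {
    stop("similarity matrix must be symmetric")
  }
  diss <- stats::as.dist(scale_max - similarity)
  hc <- stats::hclust(diss, method = linkage)
  part <- stats::cutree(hc, k = k)
  list(partition = part, merge_heights = hc$height, hclust = hc)
}

#' Score triangle-test (3-AFC) discrimination trials
#'
#' @param trials data.frame with a 0/1 `correct` column (one row per
#'   trial)
#' @return list: `proportion_correct`, `n_trials`, `chance` (1/3)
#' @export
scoreTriangle <- function(trials) {
  if (nrow(trials) < 1L) stop("need at least one trial")
  list(proportion_correct = mean(trials$correct), n_trials = nrow(trials),
       chance = 1 / 3)
}

#' Score catch-trial categorisation performance
#'
#' Accuracy over all catch trials (non-responses count as incorrect) and
#' mean reaction time over responded trials only; chance for the
#' three-alternative probe is 1/3.
#'
#' @param log data.frame with `correct` (logical/0-1) and `rt` (s; NA for
#'   non-responses) columns
#' @return list: `accuracy`, `mean_rt`, `n_trials`, `chance` (1/3)
#' @export
scoreCatch <- function(log) {
  if (nrow(log) < 1L) stop("no catch trials")
  responded <- !is.na(log$rt)
  if (!any(responded)) stop("no responded catch trials")
  correct <- as.logical(log$correct) & responded
  list(accuracy = mean(correct), mean_rt = mean(log$rt[responded]),
       n_trials = nrow(log), chance = 1 / 3)
}
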