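## Correlation-distance representational analysis.
##
## Distance between two patterns is 1 - Pearson r (0 = identical up to
## affine scaling, 2 = anticorrelated). All odor-pair distances are
## computed across pairs of *different* runs only, classed as same-odor,
## within-category or across-category, and summarised per subject-session.
## Subtracting the same-odor mean from the within- and across-category
## means cancels session- and run-level nuisance variability, leaving the
## relative categorical structure.

## cross-run distance table from a pattern matrix and its labels
.distanceTableCore <- function(B, odor, category, run) {
  if (length(unique(run)) < 2L) stop("need at least two runs")
  sds <- sqrt(colSums((B - rep(colMeans(B), each = nrow(B)))^2))
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    stop("zero-variance pattern vector (correlation undefined): odor ",
         odor[bad], ", run ", run[bad])
  }
  D <- 1 - stats::cor(B)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  cross_run <- run[idx[, 1L]] != run[idx[, 2L]]
  idx <- idx[cross_run, , drop = FALSE]
  i <- idx[, 1L]; j <- idx[, 2L]
  pair_class <- ifelse(odor[i] == odor[j], "same_odor",
                       ifelse(category[i] == category[j],
                              "within_category", "across_category"))
  out <- data.frame(odor_i = odor[i], run_i = run[i],
                    odor_j = odor[j], run_j = run[j],
                    distance = D[idx], pair_class = pair_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("PairwiseDistanceTable", class(out))
  out
}

#' All cross-run pairwise correlation distances of a pattern set
#'
#' @param patterns a [BetaPatternSet-class] (>= 2 runs)
#' @return data.frame of class `PairwiseDistanceTable`: odor_i, run_i,
#'   odor_j, run_j, distance, pair_class in
#'   {"same_odor","within_category","across_category"}
#' @export
patternDistanceMatrix <- function(patterns) {
  info <- patternInfo(patterns)
  .distanceTableCore(betaMatrix(patterns), info$odor, info$category,
                     info$run)
}

#' Distance summary straight from a run-pattern array
#'
#' Simulation-scale workhorse: applies the hemisphere-wise normalisation
#' and computes the class-mean correlation distances of one
#' subject-session directly from an odor x voxel x run array, without
#' materialising the full pattern container or pair table. Identical in
#' value to `summarizeDistances(patternDistanceMatrix(...))` on the same
#' patterns (asserted by the test suite).
#'
#' @param run_patterns odor x voxel x run array (as from
#'   [generateRunPatterns()])
#' @param hemisphere per-voxel "L"/"R" labels
#' @param categories named odor -> category map
#' @return one-row `DistanceSummary` data.frame
#' @export
distanceSummaryFromArray <- function(run_patterns, hemisphere,
                                     categories = .defaultCategories) {
  odors <- dimnames(run_patterns)[[1L]]
  n_runs <- dim(run_patterns)[3L]
  B <- do.call(cbind, lapply(seq_len(n_runs), function(r)
    t(run_patterns[, , r])))
  B <- .hemisphereScale(B, hemisphere)
  odor <- rep(odors, times = n_runs)
  run <- rep(seq_len(n_runs), each = length(odors))
  category <- unname(categories[odor])
  D <- 1 - stats::cor(B)
  ut <- upper.tri(D)
  cross <- outer(run, run, "!=") & ut
  same_odor <- outer(odor, odor, "==")
  same_cat <- outer(category, category, "==")
  m_same <- mean(D[cross & same_odor])
  m_within <- mean(D[cross & !same_odor & same_cat])
  m_across <- mean(D[cross & !same_cat])
  out <- data.frame(same = m_same, within = m_within, across = m_across,
                    adj_within = m_within - m_same,
                    adj_across = m_across - m_same)
  class(out) <- c("DistanceSummary", class(out))
  out
}

#' Summarise distances with same-odor baseline subtraction
#'
#' Averages the distance table within each pair class and subtracts the
#' same-odor mean from the within- and across-category means. Adjusted
#' values may legitimately be negative; they are relative quantities.
#'
#' @param table a [patternDistanceMatrix()] result
#' @return one-row data.frame of class `DistanceSummary`: same, within,
#'   across, adj_within, adj_across
#' @export
summarizeDistances <- function(table) {
  cls <- c("same_odor", "within_category", "across_category")
  if (!all(cls %in% table$pair_class)) {
    stop("empty pair class: ",
         paste(setdiff(cls, unique(table$pair_class)), collapse = ", "))
  }
  m <- tapply(table$distance, table$pair_class, mean)
  out <- data.frame(same = m[["same_odor"]],
                    within = m[["within_category"]],
                    across = m[["across_category"]])
  out$adj_within <- out$within - out$same
  out$adj_across <- out$across - out$same
  class(out) <- c("DistanceSummary", class(out))
  out
}

#' Per-run categorisation strength
#'
#' Strength is the mean across-category minus mean within-category
#' distance. For the per-run index each cross-run pair contributes to both
#' runs it involves, so runs are used symmetrically and the run-average of
#' the index equals the session-level difference.
#'
#' @param table a [patternDistanceMatrix()] result
#' @return data.frame: run, strength
#' @export
categorizationStrength <- function(table) {
  runs <- sort(unique(c(table$run_i, table$run_j)))
  out <- lapply(runs, function(r) {
    sub <- table[table$run_i == r | table$run_j == r, ]
    data.frame(run = r,
               strength = mean(sub$distance[sub$pair_class ==
                                              "across_category"]) -
                 mean(sub$distance[sub$pair_class == "within_category"]))
  })
  do.call(rbind, out)
}

#' Regression of per-run repetition load on categorisation strength
#'
#' For each subject, correlates the per-run percentage of category
#' repetition trials with the per-run categorisation strength; a non-zero
#' group-level mean correlation would indicate that trial-order effects
#' drive the categorical structure. Subjects with constant repetition
#' percentages are excluded (logged).
#'
#' @param rep_percent data.frame: subject, run, rep_percent
#' @param strength data.frame: subject, run, strength
#' @return list: `per_subject` (subject, r), `t`, `df`, `p` (two-tailed,
#'   vs 0), `excluded` subjects
#' @export
orderEffectRegression <- function(rep_percent, strength) {
  merged <- merge(rep_percent, strength, by = c("subject", "run"))
  excluded <- character(0L)
  per_subj <- lapply(split(merged, merged$subject), function(d) {
    if (nrow(d) < 3L) return(NULL)
    if (stats::sd(d$rep_percent) == 0) {
      excluded <<- c(excluded, as.character(d$subject[1L]))
      return(NULL)
    }
    data.frame(subject = d$subject[1L],
               r = stats::cor(d$rep_percent, d$strength))
  })
  if (length(excluded)) {
    message("excluded ", length(excluded),
            " subject(s) with constant repetition percentage")
  }
  per_subj <- do.call(rbind, per_subj)
  if (is.null(per_subj) || nrow(per_subj) < 2L) {
    stop("too few subjects with usable run-wise variation")
  }
  tt <- tTest(per_subj$r, mu = 0, tail = "two")
  list(per_subject = per_subj, t = tt$t, df = tt$df, p = tt$p,
       excluded = excluded)
}

#' Repetition-condition pattern correlations
#'
#' For each odor with at least two repetition trials and one
#' non-repetition trial, computes (1) the mean pairwise correlation among
#' repetition-condition trial patterns and (2) the mean correlation
#' between repetition and non-repetition trial patterns, averaged over
#' pairs then over odors. A difference between (1) and (2) would indicate
#' that trial order reshapes the single-trial patterns. Catch trials and
#' first-of-run trials are not analysis trials.
#'
#' @param trials a [extractTrialPatterns()] result
#' @return list: `rep_rep`, `rep_nonrep` (means over odors), `per_odor`
#'   data.frame, `skipped_odors`
#' @export
repetitionPatternCorrelations <- function(trials) {
  info <- trials$info
  ok <- !info$catch & !is.na(info$repetition)
  skipped <- character(0L)
  per_odor <- lapply(unique(info$odor), function(o) {
    ridx <- which(ok & info$odor == o & info$repetition == "rep")
    nidx <- which(ok & info$odor == o & info$repetition == "nonrep")
    if (length(ridx) < 2L || length(nidx) < 1L) {
      skipped <<- c(skipped, o)
      return(NULL)
    }
    R <- stats::cor(t(trials$patterns[ridx, , drop = FALSE]))
    rr <- mean(R[upper.tri(R)])
    C <- stats::cor(t(trials$patterns[ridx, , drop = FALSE]),
                    t(trials$patterns[nidx, , drop = FALSE]))
    data.frame(odor = o, rep_rep = rr, rep_nonrep = mean(C),
               stringsAsFactors = FALSE)
  })
  per_odor <- do.call(rbind, per_odor)
  if (length(skipped)) {
    message("skipped odor(s) without enough repetition trials: ",
            paste(skipped, collapse = ", "))
  }
  if (is.null(per_odor)) stop("no odor with enough repetition trials")
  list(rep_rep = mean(per_odor$rep_rep),
       rep_nonrep = mean(per_odor$rep_nonrep),
       per_odor = per_odor, skipped_odors = skipped)
}

#' Brain-behaviour correlation of pre-to-post changes
#'
#' Correlates subject-wise behavioural change scores against pattern-change
#' scores (e.g. fine-odor-discrimination change vs within-category distance
#' change), one-tailed in the hypothesised direction.
#'
#' @param delta_behavior,delta_pattern matched per-subject change scores
#' @param method `"spearman"` (default) or `"pearson"`
#' @param tail `"greater"` (default), `"less"` or `"two"`
#' @return list: `estimate`, `p`, `n`, `method`
#' @export
brainBehaviorChange <- function(delta_behavior, delta_pattern,
                                method = c("spearman", "pearson"),
                                tail = c("greater", "less", "two")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (length(delta_behavior) < 4L) stop("need at least four subjects")
  correlationTest(delta_behavior, delta_pattern, method = method,
                  tail = tail)
}
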