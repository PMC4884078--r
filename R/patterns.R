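## Pattern assembly: per-ROI beta pattern vectors from GLM fits, with
## hemisphere-wise normalisation, and single-trial patterns from raw
## series for the trial-order control analyses.

## z-scale each hemisphere sub-vector of each pattern column
.hemisphereScale <- function(beta, hemisphere) {
  for (h in unique(hemisphere)) {
    idx <- hemisphere == h
    x <- beta[idx, , drop = FALSE]
    n <- nrow(x)
    if (n < 2L) stop("hemisphere ", h, " has fewer than two voxels")
    x <- x - rep(colMeans(x), each = n)
    s <- sqrt(colSums(x^2) / (n - 1L))
    if (any(s == 0)) {
      stop("cannot z-score hemisphere ", h,
           " sub-vector: zero variance in pattern ",
           which(s == 0)[1L])
    }
    beta[idx, ] <- x / rep(s, each = n)
  }
  beta
}

#' Assemble hemisphere-normalised beta patterns for one ROI
#'
#' Collects the condition betas of every run into one voxel x pattern
#' matrix (6 odors x 6 runs = 36 patterns under the default design), scales
#' the left- and right-hemisphere sub-vector of each pattern to mean 0 and
#' standard deviation 1 separately, and concatenates them — so mean signal
#' and lateralisation cannot carry pattern information.
#'
#' @param fits list of `GlmFit` objects, one per run (names or order give
#'   the run index)
#' @param hemisphere per-voxel "L"/"R" labels
#' @param categories named odor -> category map
#' @param conditions odor labels to extract; default from the first fit's
#'   design
#' @param subject,session,group,roi metadata labels
#' @return a [BetaPatternSet-class]
#' @export
assembleBetaPatterns <- function(fits, hemisphere,
                                 categories = .defaultCategories,
                                 conditions = NULL, subject = "s01",
                                 session = "pre", group = "placebo",
                                 roi = "PPC") {
  stopifnot(length(fits) >= 1L)
  if (is.null(conditions)) conditions <- fits[[1L]]$design$conditions
  cols <- list(); odor <- character(0L); run <- integer(0L)
  for (r in seq_along(fits)) {
    b <- fits[[r]]$beta
    missing <- setdiff(conditions, rownames(b))
    if (length(missing)) {
      stop("missing condition beta(s) in run ", r, ": ",
           paste(missing, collapse = ", "))
    }
    cols <- c(cols, list(t(b[conditions, , drop = FALSE])))
    odor <- c(odor, conditions)
    run <- c(run, rep(r, length(conditions)))
  }
  beta <- do.call(cbind, cols)
  stopifnot(nrow(beta) == length(hemisphere))
  beta <- .hemisphereScale(beta, hemisphere)
  BetaPatternSet(beta, odor = odor,
                 category = unname(categories[odor]), run = run,
                 hemisphere = hemisphere, subject = subject,
                 session = session, group = group, roi = roi,
                 normalized = TRUE)
}

#' Build a BetaPatternSet directly from run-level pattern arrays
#'
#' Convenience constructor for simulation studies that work at the pattern
#' level (odor x voxel x run arrays from [generateRunPatterns()]), applying
#' the same hemisphere-wise normalisation as [assembleBetaPatterns()].
#'
#' @param run_patterns odor x voxel x run array
#' @param hemisphere per-voxel "L"/"R" labels
#' @inheritParams assembleBetaPatterns
#' @return a [BetaPatternSet-class]
#' @export
patternSetFromArray <- function(run_patterns, hemisphere,
                                categories = .defaultCategories,
                                subject = "s01", session = "pre",
                                group = "placebo", roi = "PPC") {
  odors <- dimnames(run_patterns)[[1L]]
  n_runs <- dim(run_patterns)[3L]
  beta <- do.call(cbind, lapply(seq_len(n_runs), function(r)
    t(run_patterns[, , r])))
  odor <- rep(odors, times = n_runs)
  run <- rep(seq_len(n_runs), each = length(odors))
  beta <- .hemisphereScale(beta, hemisphere)
  BetaPatternSet(beta, odor = odor, category = unname(categories[odor]),
                 run = run, hemisphere = hemisphere, subject = subject,
                 session = session, group = group, roi = roi,
                 normalized = TRUE)
}

#' Extract single-trial patterns from a raw voxel time series
#'
#' Detrends each voxel series with the cosine high-pass projection (cutoff
#' 0.01 Hz), then averages the detrended signal over a lagged response
#' window after each trial onset (default scans 2-4 post-onset, 4.6-9.2 s
#' at TR 2.3 s) to give one voxel vector per trial. Each trial is assigned
#' a repetition condition from the category of the preceding trial
#' (first-of-run trials are undefined); catch trials count as predecessors
#' but are flagged and excluded as analysis trials.
#'
#' @param timeseries n_scans x n_voxels matrix for one run
#' @param events event-table rows for the run, ordered by onset
#' @param tr repetition time (s)
#' @param highpass_hz detrending cutoff frequency (default 0.01 Hz)
#' @param window_scans post-onset scan offsets averaged into the trial
#'   vector (default 2:4)
#' @return list of class `TrialPatternSet`: `patterns` (trial x voxel),
#'   `info` (data.frame: trial, odor, category, catch, repetition in
#'   {"rep","nonrep",NA}, dropped), `dropped` trial indices whose window
#'   exceeded the run
#' @export
extractTrialPatterns <- function(timeseries, events, tr = 2.3,
                                 highpass_hz = 0.01, window_scans = 2:4) {
  Y <- as.matrix(timeseries)
  n_scans <- nrow(Y)
  stopifnot(length(unique(events$run)) == 1L,
            !is.unsorted(events$onset))
  ## cosine detrending: project out drift components with period above
  ## 1/highpass_hz seconds, and the mean
  drift <- cbind(1, dctBasis(n_scans, tr, cutoff = 1 / highpass_hz))
  Y <- qr.resid(qr(drift), Y)
  onset_scan <- floor(events$onset / tr) + 1L
  rows <- lapply(seq_len(nrow(events)), function(i) {
    idx <- onset_scan[i] + window_scans
    if (max(idx) > n_scans) return(NULL)
    colMeans(Y[idx, , drop = FALSE])
  })
  dropped <- which(vapply(rows, is.null, logical(1L)))
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " trial(s) whose response window exceeded the run")
  }
  keep <- setdiff(seq_len(nrow(events)), dropped)
  patterns <- do.call(rbind, rows[keep])
  prev_cat <- c(NA_character_, events$category[-nrow(events)])
  first_of_run <- events$trial == min(events$trial)
  repetition <- ifelse(first_of_run, NA_character_,
                       ifelse(prev_cat == events$category, "rep", "nonrep"))
  info <- data.frame(trial = events$trial[keep], odor = events$odor[keep],
                     category = events$category[keep],
                     catch = events$catch[keep],
                     repetition = repetition[keep],
                     stringsAsFactors = FALSE)
  structure(list(patterns = patterns, info = info, dropped = dropped),
            class = "TrialPatternSet")
}

#' Census of category repetition and non-repetition trials
#'
#' Counts, over all trials with a defined predecessor (first-of-run trials
#' excluded), how many were preceded by a same-category trial (repetition)
#' versus a different-category trial (non-repetition), per session.
#'
#' @param events a session event table ordered by onset within run
#' @return data.frame: session, n_rep, n_nonrep, n_first (excluded),
#'   rep_fraction = n_rep / (n_rep + n_nonrep)
#' @export
repetitionTrialCensus <- function(events) {
  out <- lapply(split(events, events$session), function(ev) {
    n_rep <- 0L; n_nonrep <- 0L; n_first <- 0L
    for (r in unique(ev$run)) {
      run_ev <- ev[ev$run == r, ]
      run_ev <- run_ev[order(run_ev$onset), ]
      n_first <- n_first + 1L
      if (nrow(run_ev) > 1L) {
        same <- run_ev$category[-1L] == run_ev$category[-nrow(run_ev)]
        n_rep <- n_rep + sum(same)
        n_nonrep <- n_nonrep + sum(!same)
      }
    }
    data.frame(session = ev$session[1L], n_rep = n_rep,
               n_nonrep = n_nonrep, n_first = n_first,
               rep_fraction = n_rep / (n_rep + n_nonrep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
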