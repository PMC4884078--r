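## Whole-cohort simulation: two groups (18 placebo / 14 drug by default),
## two sessions, with per-subject designs, planted pattern geometry,
## optional sniff traces and BOLD series, and behavioural ratings. All
## per-subject randomness derives deterministically from the global seed,
## so identical (config, seed) gives an identical cohort.

#' Simulate a synthetic cohort
#'
#' @param design a [studyDesignConfig()]
#' @param geometry a [patternGeometry()] (planted effects included)
#' @param noise a [boldNoise()] (used when `level = "bold"`)
#' @param sniff a [sniffModel()] (used when `level = "bold"`)
#' @param ratings a [ratingsConfig()]
#' @param n_placebo,n_drug group sizes (defaults 18 and 14)
#' @param sessions session labels (default `c("pre", "post")`)
#' @param level `"beta"` generates run-level voxel patterns directly from
#'   the geometry (fast; for pattern-analysis studies); `"bold"`
#'   additionally synthesises sniff traces and voxel time series so the
#'   GLM stage can be exercised
#' @param seed integer seed governing the whole cohort
#' @return list of class `SyntheticCohort`: `subjects` (list; each has
#'   `subject`, `group`, and per-session `events`, `truth`,
#'   `run_patterns` and, at bold level, `sniff_traces`, `bold`),
#'   `hemisphere`, the configs, and `seed`
#' @export
simulateCohort <- function(design = studyDesignConfig(),
                           geometry = patternGeometry(),
                           noise = boldNoise(), sniff = sniffModel(),
                           ratings = ratingsConfig(),
                           n_placebo = 18L, n_drug = 14L,
                           sessions = c("pre", "post"),
                           level = c("beta", "bold"), seed = 1L) {
  level <- match.arg(level)
  groups <- rep(c("placebo", "drug"), c(n_placebo, n_drug))
  n_scans <- floor(design$run_duration_s / design$tr)
  subjects <- lapply(seq_along(groups), function(s) {
    sid <- sprintf("s%02d", s)
    per_session <- lapply(seq_along(sessions), function(si) {
      base <- .deriveSeed(seed, s * 97L + si * 13L)
      events <- generateTrialSequence(design, seed = base,
                                      session = sessions[si],
                                      subject = sid, group = groups[s])
      truth <- generatePatternGeometry(geometry, odors = design$odors,
                                       categories = design$categories,
                                       group = groups[s],
                                       session = sessions[si],
                                       seed = base + 1L)
      out <- list(events = events, truth = truth)
      out$run_patterns <- generateRunPatterns(truth, design$n_runs,
                                              seed = base + 2L)
      if (level == "bold") {
        out$sniff_traces <- lapply(seq_len(design$n_runs), function(r) {
          generateSniffTrace(events[events$run == r, ], sniff,
                             seed = base + 10L + r,
                             run_duration_s = design$run_duration_s)
        })
        out$bold <- lapply(seq_len(design$n_runs), function(r) {
          synthesizeBold(events[events$run == r, ],
                         out$run_patterns[, , r], noise = noise,
                         sniff_truth = out$sniff_traces[[r]]$truth,
                         tr = design$tr, n_scans = n_scans,
                         seed = base + 40L + r)
        })
      }
      out$ratings <- generateRatings(ratings, odors = design$odors,
                                     categories = design$categories,
                                     subject = sid,
                                     session = sessions[si],
                                     group = groups[s], events = events,
                                     seed = base + 80L)
      out
    })
    names(per_session) <- sessions
    list(subject = sid, group = groups[s], sessions = per_session)
  })
  structure(list(subjects = subjects,
                 hemisphere = rep(c("L", "R"),
                                  each = geometry$n_voxels_per_hemisphere),
                 design = design, geometry = geometry, noise = noise,
                 sniff = sniff, ratings = ratings, level = level,
                 sessions = sessions, seed = seed),
            class = "SyntheticCohort")
}
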