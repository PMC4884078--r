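## Study design configuration and pseudorandom trial-sequence generation.
##
## The default configuration reproduces the event structure of a two-session
## olfactory categorisation study: six 8-minute runs of 28 trials, six odors
## in three perceptual categories (two exemplars each), a fixed 13-s
## stimulus-onset asynchrony, and four catch trials per run spaced every
## 4-8 trials. Catch trials probe category judgements behaviourally and are
## excluded from all pattern analyses.

.defaultOdors <- c("C1", "C2", "M1", "M2", "W1", "W2")
.defaultCategories <- c(C1 = "citrus", C2 = "citrus",
                        M1 = "mint",   M2 = "mint",
                        W1 = "wood",   W2 = "wood")

#' Study design configuration
#'
#' Bundles the trial-level design parameters of an event-related odor
#' categorisation session.
#'
#' @param n_runs runs per session (default 6)
#' @param trials_per_run trials per run (default 28)
#' @param n_catch_per_run catch trials per run (default 4)
#' @param soa stimulus-onset asynchrony in seconds (default 13)
#' @param stim_duration odor pulse duration in seconds (default 1.5)
#' @param odors odor labels (default six: C1 C2 M1 M2 W1 W2)
#' @param categories named character vector mapping odor -> category
#' @param catch_spacing integer bounds on the trial-count gap between
#'   consecutive catch trials (default c(4, 8))
#' @param tr scan repetition time in seconds (default 2.3)
#' @param run_duration_s run length in seconds (default 480, an 8-min run)
#' @param no_immediate_repeat forbid the same odor on consecutive trials
#'   (default FALSE; the pseudorandomisation is otherwise a uniform
#'   balance-constrained permutation)
#' @return a list of class `StudyDesignConfig`
#' @export
studyDesignConfig <- function(n_runs = 6L, trials_per_run = 28L,
                              n_catch_per_run = 4L, soa = 13,
                              stim_duration = 1.5,
                              odors = .defaultOdors,
                              categories = .defaultCategories,
                              catch_spacing = c(4L, 8L), tr = 2.3,
                              run_duration_s = 480,
                              no_immediate_repeat = FALSE) {
  stopifnot(n_runs >= 1L, trials_per_run >= 1L,
            n_catch_per_run >= 0L, n_catch_per_run <= trials_per_run,
            soa > 0, stim_duration > 0, tr > 0,
            length(catch_spacing) == 2L, catch_spacing[1L] >= 1L,
            catch_spacing[2L] >= catch_spacing[1L],
            length(odors) >= 1L, !anyDuplicated(odors),
            all(odors %in% names(categories)))
  if ((n_runs * trials_per_run) %% length(odors) != 0L) {
    stop("n_runs * trials_per_run must be a multiple of the number of odors")
  }
  structure(list(n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 n_catch_per_run = as.integer(n_catch_per_run),
                 soa = soa, stim_duration = stim_duration,
                 odors = odors, categories = categories[odors],
                 catch_spacing = as.integer(catch_spacing), tr = tr,
                 run_duration_s = run_duration_s,
                 no_immediate_repeat = isTRUE(no_immediate_repeat)),
            class = "StudyDesignConfig")
}

## Per-run odor count matrix (odor x run). Each odor appears
## total/n_runs times on average; when the per-run share is fractional
## (28 trials / 6 odors), counts are balanced to floor/ceiling values with
## exact row and column sums, randomised by a cyclic assignment under a
## random odor-to-run permutation.
.odorCountMatrix <- function(config) {
  n_od <- length(config$odors)
  total_per_odor <- config$n_runs * config$trials_per_run / n_od
  base <- config$trials_per_run %/% n_od     # low count per run
  n_low_runs_per_odor <- config$n_runs * (base + 1L) - total_per_odor
  counts <- matrix(base + 1L, nrow = n_od, ncol = config$n_runs,
                   dimnames = list(config$odors, NULL))
  if (n_low_runs_per_odor > 0L) {
    if ((n_low_runs_per_odor * n_od) %% config$n_runs != 0L) {
      stop("infeasible design: per-run odor balance cannot be achieved ",
           "with trials_per_run = ", config$trials_per_run,
           " and ", n_od, " odors over ", config$n_runs, " runs")
    }
    ## odor o takes the low count in a block of n_low consecutive runs
    ## (cyclically) starting at a round-robin offset over a random odor
    ## permutation, so every run is covered by exactly
    ## n_low * n_od / n_runs odors
    offs <- (sample.int(n_od) - 1L) %% config$n_runs + 1L
    for (o in seq_len(n_od)) {
      runs_low <- (offs[o] + seq_len(n_low_runs_per_odor) - 2L) %%
        config$n_runs + 1L
      counts[o, runs_low] <- base
    }
    if (any(colSums(counts) != config$trials_per_run)) {
      stop("infeasible design: could not balance per-run odor counts")
    }
  }
  counts
}

## catch positions: consecutive gaps drawn uniformly within the spacing
## bounds (the gap before the first catch counts from the run start)
.catchPositions <- function(config) {
  k <- config$n_catch_per_run
  if (k == 0L) return(integer(0L))
  lo <- config$catch_spacing[1L]; hi <- config$catch_spacing[2L]
  if (k * lo > config$trials_per_run) {
    stop("infeasible design: ", k, " catch trials with minimum spacing ", lo,
         " do not fit in ", config$trials_per_run, " trials")
  }
  for (i in seq_len(1000L)) {
    gaps <- sample(seq.int(lo, hi), k, replace = TRUE)
    pos <- cumsum(gaps)
    if (pos[k] <= config$trials_per_run) return(pos)
  }
  stop("infeasible design: catch spacing bounds ", lo, "-", hi,
       " rarely fit ", k, " catch trials into ", config$trials_per_run,
       " trials")
}

#' Generate a pseudorandom trial sequence for one session
#'
#' Produces one row per trial with onsets on a fixed SOA grid, per-run odor
#' counts balanced so every odor is presented equally often across the
#' session, and catch trials spaced within the configured bounds.
#'
#' @param config a [studyDesignConfig()]
#' @param seed optional integer seed (local RNG scope)
#' @param session,subject,group label columns attached to the table
#' @return a `data.frame` (an event table) with columns `onset`, `duration`,
#'   `odor`, `category`, `catch`, `trial`, `run`, `session`, `subject`,
#'   `group`
#' @export
generateTrialSequence <- function(config = studyDesignConfig(), seed = NULL,
                                  session = "pre", subject = "s01",
                                  group = "placebo") {
  .withSeed(seed, {
    counts <- .odorCountMatrix(config)
    runs <- lapply(seq_len(config$n_runs), function(r) {
      labels <- rep(config$odors, counts[, r])
      seq_ok <- FALSE
      for (i in seq_len(1000L)) {
        odor <- sample(labels)
        if (!config$no_immediate_repeat ||
            !any(odor[-1L] == odor[-length(odor)])) { seq_ok <- TRUE; break }
      }
      if (!seq_ok) {
        stop("infeasible design: no-immediate-repeat constraint unmet ",
             "after 1000 attempts in run ", r)
      }
      catch <- rep(FALSE, config$trials_per_run)
      catch[.catchPositions(config)] <- TRUE
      data.frame(onset = (seq_len(config$trials_per_run) - 1L) * config$soa,
                 duration = config$stim_duration,
                 odor = odor,
                 category = unname(config$categories[odor]),
                 catch = catch,
                 trial = seq_len(config$trials_per_run),
                 run = r, stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, runs)
    events$session <- session
    events$subject <- subject
    events$group <- group
    events
  })
}
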