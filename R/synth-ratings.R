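## Behavioural data synthesis: category descriptor ratings, pairwise
## similarity ratings, triangle-test (3-AFC) discrimination trials, catch
## responses and sleepiness scores. Defaults plant the category structure
## at magnitudes typical of highly familiar odor sets: descriptor
## within-minus-across margin ~7.5 on a 0-10 visual-analogue scale,
## similarity margin ~4.2, triangle accuracy ~0.7, catch accuracy ~0.85.

#' Ratings generator configuration
#'
#' @param descriptor_base mean descriptor rating for a non-matching
#'   category (0-10 VAS)
#' @param descriptor_margin planted within-minus-across descriptor margin
#' @param similarity_base mean similarity of across-category pairs
#' @param similarity_margin planted within-minus-across similarity margin
#' @param rating_noise_sd Gaussian noise sd on individual ratings
#' @param triangle_accuracy planted probability of a correct 3-AFC response
#' @param n_triangle_trials triangle-test trials per subject-session
#' @param catch_accuracy planted probability of a correct catch response
#' @param catch_rt_meanlog,catch_rt_sdlog lognormal RT parameters (s)
#' @param sleepiness_base baseline Stanford-sleepiness score (1-7)
#' @param sleepiness_shift optional data.frame (`group`, `session`,
#'   `shift`) of planted mean sleepiness shifts
#' @param scale_max VAS maximum (default 10)
#' @return list of class `RatingsConfig`
#' @export
ratingsConfig <- function(descriptor_base = 1.2, descriptor_margin = 7.5,
                          similarity_base = 2.7, similarity_margin = 4.2,
                          rating_noise_sd = 1, triangle_accuracy = 0.7,
                          n_triangle_trials = 12L, catch_accuracy = 0.85,
                          catch_rt_meanlog = log(3.2), catch_rt_sdlog = 0.3,
                          sleepiness_base = 2.2, sleepiness_shift = NULL,
                          scale_max = 10) {
  stopifnot(descriptor_base >= 0, similarity_base >= 0,
            rating_noise_sd >= 0,
            triangle_accuracy >= 0, triangle_accuracy <= 1,
            catch_accuracy >= 0, catch_accuracy <= 1, scale_max > 0)
  structure(list(descriptor_base = descriptor_base,
                 descriptor_margin = descriptor_margin,
                 similarity_base = similarity_base,
                 similarity_margin = similarity_margin,
                 rating_noise_sd = rating_noise_sd,
                 triangle_accuracy = triangle_accuracy,
                 n_triangle_trials = as.integer(n_triangle_trials),
                 catch_accuracy = catch_accuracy,
                 catch_rt_meanlog = catch_rt_meanlog,
                 catch_rt_sdlog = catch_rt_sdlog,
                 sleepiness_base = sleepiness_base,
                 sleepiness_shift = sleepiness_shift,
                 scale_max = scale_max),
            class = "RatingsConfig")
}

.clipScale <- function(x, scale_max) pmin(pmax(x, 0), scale_max)

#' Generate a behavioural ratings bundle for one subject-session
#'
#' @param config a [ratingsConfig()]
#' @param odors odor labels
#' @param categories named odor -> category map
#' @param subject,session,group labels attached to outputs
#' @param events optional event table supplying the session's catch trials
#'   (one response row is generated per catch trial); if NULL, 24 catch
#'   responses are generated
#' @param seed optional integer seed
#' @return list of class `RatingsBundle`: `descriptor` (odor x descriptor
#'   data.frame), `similarity` (odor-pair data.frame), `triangle`
#'   (trial-level 0/1), `catch` (trial, true category, response, correct,
#'   rt), `sleepiness` (integer 1-7), plus the label fields
#' @export
generateRatings <- function(config = ratingsConfig(), odors = .defaultOdors,
                            categories = .defaultCategories,
                            subject = "s01", session = "pre",
                            group = "placebo", events = NULL, seed = NULL) {
  .withSeed(seed, {
    cats <- unique(unname(categories[odors]))
    stopifnot(length(cats) >= 2L)
    ## descriptor ratings: odor x category-descriptor grid
    grid <- expand.grid(odor = odors, descriptor = cats,
                        stringsAsFactors = FALSE)
    match_cat <- unname(categories[grid$odor]) == grid$descriptor
    grid$rating <- .clipScale(
      config$descriptor_base + config$descriptor_margin * match_cat +
        stats::rnorm(nrow(grid), 0, config$rating_noise_sd),
      config$scale_max)
    ## pairwise similarity over all unordered odor pairs
    pairs <- t(utils::combn(odors, 2L))
    within <- unname(categories[pairs[, 1L]]) ==
      unname(categories[pairs[, 2L]])
    sim <- data.frame(odor_i = pairs[, 1L], odor_j = pairs[, 2L],
                      within_category = within,
                      rating = .clipScale(
                        config$similarity_base +
                          config$similarity_margin * within +
                          stats::rnorm(nrow(pairs), 0,
                                       config$rating_noise_sd),
                        config$scale_max),
                      stringsAsFactors = FALSE)
    triangle <- data.frame(trial = seq_len(config$n_triangle_trials),
                           correct = stats::rbinom(config$n_triangle_trials,
                                                   1L,
                                                   config$triangle_accuracy))
    ## catch responses: correct with planted probability, otherwise a
    ## uniform choice among the two wrong categories
    if (!is.null(events)) {
      catch_ev <- events[events$catch, , drop = FALSE]
      true_cat <- unname(categories[catch_ev$odor])
    } else {
      true_cat <- sample(cats, 24L, replace = TRUE)
    }
    n_catch <- length(true_cat)
    is_corr <- stats::rbinom(n_catch, 1L, config$catch_accuracy) == 1L
    resp <- vapply(seq_len(n_catch), function(i) {
      if (is_corr[i]) true_cat[i] else sample(setdiff(cats, true_cat[i]), 1L)
    }, character(1L))
    catch <- data.frame(trial = seq_len(n_catch), true_category = true_cat,
                        response = resp, correct = resp == true_cat,
                        rt = stats::rlnorm(n_catch, config$catch_rt_meanlog,
                                           config$catch_rt_sdlog),
                        stringsAsFactors = FALSE)
    sleep_mu <- config$sleepiness_base
    if (!is.null(config$sleepiness_shift)) {
      hit <- config$sleepiness_shift$group == group &
        config$sleepiness_shift$session == session
      if (any(hit)) sleep_mu <- sleep_mu +
          config$sleepiness_shift$shift[which(hit)[1L]]
    }
    sleepiness <- as.integer(pmin(pmax(round(
      stats::rnorm(1L, sleep_mu, 0.8)), 1L), 7L))
    structure(list(descriptor = grid, similarity = sim, triangle = triangle,
                   catch = catch, sleepiness = sleepiness,
                   subject = subject, session = session, group = group,
                   categories = categories[odors],
                   scale_max = config$scale_max),
              class = "RatingsBundle")
  })
}
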