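## Planted representational geometry.
##
## Voxel patterns are built from independent Gaussian variance components:
##
##   beta(odor)        = session_common + sigma_cat * u(category)
##                                      + sigma_odor * v(odor)
##   pattern(odor,run) = beta(odor) + sigma_run * e(run, odor)
##
## with every component drawn i.i.d. N(0,1) per voxel per subject. With
## centred components the expected Pearson correlation between two run
## patterns is shared variance over total variance, so (with
## session_common = 0):
##
##   same odor       (sigma_cat^2 + sigma_odor^2) / T
##   within category  sigma_cat^2 / T
##   across category  0
##   where T = sigma_cat^2 + sigma_odor^2 + sigma_run^2.
##
## Group-by-session "drug" effects are planted as multiplicative rescalings
## of sigma_odor and/or sigma_cat in the designated group and session, which
## moves within- and across-category correlation distances in closed form.

#' Pattern geometry configuration
#'
#' @param n_voxels_per_hemisphere voxels per hemisphere (default 100)
#' @param sigma_cat std of the category-shared pattern component
#' @param sigma_odor std of the odor-specific component
#' @param sigma_run std of run-level pattern noise
#' @param sigma_session std of the session-common component shared by all
#'   odors (cancelled by same-odor baseline subtraction downstream)
#' @param planted_effects optional data.frame with columns `group`,
#'   `session`, `odor_mult`, `cat_mult`: multiplicative changes applied to
#'   `sigma_odor` / `sigma_cat` for matching group x session cells
#' @return a list of class `PatternGeometry`
#' @export
patternGeometry <- function(n_voxels_per_hemisphere = 100L,
                            sigma_cat = 1, sigma_odor = 1, sigma_run = 1,
                            sigma_session = 0, planted_effects = NULL) {
  stopifnot(n_voxels_per_hemisphere >= 1L, sigma_cat >= 0, sigma_odor >= 0,
            sigma_run >= 0, sigma_session >= 0)
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("group", "session", "odor_mult", "cat_mult") %in%
                    names(planted_effects)))
  }
  structure(list(n_voxels_per_hemisphere = as.integer(n_voxels_per_hemisphere),
                 sigma_cat = sigma_cat, sigma_odor = sigma_odor,
                 sigma_run = sigma_run, sigma_session = sigma_session,
                 planted_effects = planted_effects),
            class = "PatternGeometry")
}

#' Default planted drug-effect table
#'
#' The package's standard planted group-by-session effect: the placebo
#' group's post session multiplies the odor-specific component by
#' `odor_mult`, i.e. within-category pattern separation emerges over time
#' in the control group and is absent under the drug. With unit sigmas the
#' default 1.3 raises the expected adjusted within-category distance from
#' 1/3 to about 0.46 in that cell — a moderate-to-large planted effect.
#'
#' @param odor_mult multiplier on `sigma_odor` (default 1.3)
#' @param cat_mult multiplier on `sigma_cat` (default 1)
#' @param group,session cell receiving the effect
#' @return data.frame usable as `planted_effects` in [patternGeometry()]
#' @export
plantedDrugEffects <- function(odor_mult = 1.3, cat_mult = 1,
                               group = "placebo", session = "post") {
  data.frame(group = group, session = session, odor_mult = odor_mult,
             cat_mult = cat_mult, stringsAsFactors = FALSE)
}

## effective sigmas for one group x session cell
.effectiveSigmas <- function(geom, group, session) {
  s_odor <- geom$sigma_odor; s_cat <- geom$sigma_cat
  pe <- geom$planted_effects
  if (!is.null(pe)) {
    hit <- pe$group == group & pe$session == session
    if (any(hit)) {
      s_odor <- s_odor * pe$odor_mult[which(hit)[1L]]
      s_cat <- s_cat * pe$cat_mult[which(hit)[1L]]
    }
  }
  list(sigma_odor = s_odor, sigma_cat = s_cat)
}

#' Expected pattern correlations under a geometry
#'
#' Closed-form expected Pearson correlations (large-voxel limit) between
#' cross-run patterns for same-odor, within-category and across-category
#' pairs, for one group x session cell.
#'
#' @param geom a [patternGeometry()]
#' @param group,session cell whose (possibly planted-effect-rescaled)
#'   sigmas apply
#' @return named numeric vector `same`, `within`, `across`
#' @export
expectedPatternCorrelations <- function(geom, group = "placebo",
                                        session = "pre") {
  s <- .effectiveSigmas(geom, group, session)
  tot <- s$sigma_cat^2 + s$sigma_odor^2 + geom$sigma_run^2 +
    geom$sigma_session^2
  if (tot == 0) return(c(same = NA_real_, within = NA_real_,
                         across = NA_real_))
  c(same = (geom$sigma_session^2 + s$sigma_cat^2 + s$sigma_odor^2) / tot,
    within = (geom$sigma_session^2 + s$sigma_cat^2) / tot,
    across = geom$sigma_session^2 / tot)
}

#' Generate a true beta map for one subject-session
#'
#' Draws the session-level odor x voxel coefficient map per hemisphere from
#' the variance-component model. Run-level noise is added separately by
#' [generateRunPatterns()] (or realised through the BOLD forward model).
#'
#' @param geom a [patternGeometry()]
#' @param odors odor labels
#' @param categories named map odor -> category
#' @param group,session cell labels used to resolve planted effects
#' @param seed optional integer seed
#' @return list of class `TrueBetaMap`: `beta` (odor x voxel matrix over
#'   both hemispheres), `hemisphere` (voxel-wise "L"/"R"), `sigmas` used
#' @export
generatePatternGeometry <- function(geom, odors = .defaultOdors,
                                    categories = .defaultCategories,
                                    group = "placebo", session = "pre",
                                    seed = NULL) {
  .withSeed(seed, {
    nv <- 2L * geom$n_voxels_per_hemisphere
    s <- .effectiveSigmas(geom, group, session)
    cats <- unique(unname(categories[odors]))
    sess_common <- geom$sigma_session * stats::rnorm(nv)
    u <- matrix(stats::rnorm(length(cats) * nv), length(cats), nv,
                dimnames = list(cats, NULL))
    v <- matrix(stats::rnorm(length(odors) * nv), length(odors), nv,
                dimnames = list(odors, NULL))
    beta <- t(vapply(odors, function(o) {
      sess_common + s$sigma_cat * u[categories[[o]], ] +
        s$sigma_odor * v[o, ]
    }, numeric(nv)))
    rownames(beta) <- odors
    structure(list(beta = beta,
                   hemisphere = rep(c("L", "R"),
                                    each = geom$n_voxels_per_hemisphere),
                   sigmas = c(sigma_cat = s$sigma_cat,
                              sigma_odor = s$sigma_odor,
                              sigma_run = geom$sigma_run,
                              sigma_session = geom$sigma_session)),
              class = "TrueBetaMap")
  })
}

#' Realise per-run patterns from a true beta map
#'
#' Adds independent run-level Gaussian pattern noise to the session-level
#' map, giving the odor x run voxel patterns whose correlation structure
#' the distance analysis measures.
#'
#' @param truth a `TrueBetaMap` from [generatePatternGeometry()]
#' @param n_runs number of runs
#' @param seed optional integer seed
#' @return 3-d array (odor x voxel x run)
#' @export
generateRunPatterns <- function(truth, n_runs = 6L, seed = NULL) {
  .withSeed(seed, {
    beta <- truth$beta
    out <- array(stats::rnorm(length(beta) * n_runs,
                              sd = truth$sigmas[["sigma_run"]]),
                 dim = c(nrow(beta), ncol(beta), n_runs),
                 dimnames = list(rownames(beta), NULL, NULL))
    out + as.vector(beta)                  # recycles over runs
    })
}
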