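# Shared fixtures and independent oracles for the test suite.

defaultOdors <- c("C1", "C2", "M1", "M2", "W1", "W2")
defaultCategories <- c(C1 = "citrus", C2 = "citrus", M1 = "mint",
                       M2 = "mint", W1 = "wood", W2 = "wood")
hem200 <- rep(c("L", "R"), each = 100L)

# one subject-session pattern set from a geometry (fast path for fixtures)
makePatternSet <- function(geom = patternGeometry(100L), seed = 1L,
                           n_runs = 6L, group = "placebo",
                           session = "pre") {
  truth <- generatePatternGeometry(geom, group = group, session = session,
                                   seed = seed)
  rp <- generateRunPatterns(truth, n_runs, seed = seed + 5000L)
  patternSetFromArray(rp, rep(c("L", "R"),
                              each = geom$n_voxels_per_hemisphere),
                      group = group, session = session)
}

# brute-force correlation-distance oracle: direct loops, no shared code
# with the package's distance machinery
bruteDistanceTable <- function(B, odor, category, run) {
  n <- ncol(B)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (run[i] == run[j]) next
      x <- B[, i]; y <- B[, j]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      cls <- if (odor[i] == odor[j]) "same_odor"
      else if (category[i] == category[j]) "within_category"
      else "across_category"
      rows[[length(rows) + 1L]] <- data.frame(
        odor_i = odor[i], run_i = run[i], odor_j = odor[j],
        run_j = run[j], distance = 1 - r, pair_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# independent mixed-ANOVA oracle via car's multivariate repeated-measures
# machinery (univariate mixed-model tables with GG epsilon)
carMixedAnova <- function(data, dv, subject, between = NULL, within) {
  cell <- interaction(data[within], sep = ".", lex.order = FALSE)
  w <- tapply(data[[dv]], list(as.character(data[[subject]]),
                               as.character(cell)), mean)
  lev <- lapply(within, function(x) unique(as.character(data[[x]])))
  names(lev) <- within
  grid <- expand.grid(lev, stringsAsFactors = TRUE)
  key <- do.call(paste, c(lapply(grid, as.character), list(sep = ".")))
  w <- w[, key, drop = FALSE]
  idata <- as.data.frame(lapply(grid, factor))
  if (!is.null(between)) {
    g <- factor(tapply(as.character(data[[between]]),
                       as.character(data[[subject]]),
                       function(x) x[1L])[rownames(w)])
    mlm <- stats::lm(w ~ g, contrasts = list(g = "contr.sum"))
  } else {
    mlm <- stats::lm(w ~ 1)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  aa <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(aa, multivariate = FALSE))
  ut <- s$univariate.tests
  data.frame(effect = rownames(ut), F = ut[, "F value"],
             df1 = ut[, "num Df"], df2 = ut[, "den Df"],
             p = ut[, "Pr(>F)"], stringsAsFactors = FALSE)
}

# map package effect names (group:w1 etc.) onto car's (g:w1)
matchCarEffect <- function(effect, between) {
  e <- sub(paste0("^", between, ":"), "g:", effect)
  if (!is.null(between) && e == between) e <- "g"
  e
}

# random long-format mixed dataset generator for oracle-equivalence checks
randomMixedData <- function(n_per_group = c(7L, 5L), within_levels,
                            seed = 1L) {
  set.seed(seed)
  n <- sum(n_per_group)
  subj <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("a", "b"), n_per_group)
  args <- c(list(subject = subj), within_levels,
            list(stringsAsFactors = FALSE))
  d <- do.call(expand.grid, args)
  d$group <- grp[match(d$subject, subj)]
  d$value <- rnorm(nrow(d))
  d
}

# exhaustive best 3-partition of 6 items under block dissimilarity: the
# partition minimising total within-cluster dissimilarity, enumerated
bestThreePartition <- function(diss) {
  items <- rownames(diss)
  best <- NULL; best_cost <- Inf
  # enumerate set partitions of 6 items into 3 nonempty blocks via
  # restricted growth strings
  grow <- function(assign, next_item, max_used) {
    if (next_item > length(items)) {
      if (max_used == 3L) {
        cost <- 0
        for (k in 1:3) {
          idx <- which(assign == k)
          if (length(idx) > 1L) {
            cost <- cost + sum(diss[idx, idx][upper.tri(diss[idx, idx])])
          }
        }
        if (cost < best_cost) { best_cost <<- cost; best <<- assign }
      }
      return(invisible())
    }
    for (k in seq_len(min(max_used + 1L, 3L))) {
      grow(c(assign, k), next_item + 1L, max(max_used, k))
    }
  }
  grow(integer(0L), 1L, 0L)
  names(best) <- items
  best
}

# partitions agree up to cluster relabelling
samePartition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
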