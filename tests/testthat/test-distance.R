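test_that("correlation distance has its defining endpoint values", {
  # two runs, identical / sign-flipped patterns across runs
  v <- rnorm(40L)
  w <- rnorm(40L)
  rp <- array(0, dim = c(2L, 40L, 2L),
              dimnames = list(c("C1", "C2"), NULL, NULL))
  rp[1L, , 1L] <- v; rp[1L, , 2L] <- v      # same odor, identical
  rp[2L, , 1L] <- w; rp[2L, , 2L] <- -w     # same odor, anticorrelated
  B <- cbind(v, w, v, -w)
  tab <- odorMVPA:::.distanceTableCore(
    B, odor = c("C1", "C2", "C1", "C2"),
    category = rep("citrus", 4L), run = c(1L, 1L, 2L, 2L))
  same <- tab[tab$odor_i == tab$odor_j, ]
  d_C1 <- same$distance[same$odor_i == "C1"]
  d_C2 <- same$distance[same$odor_i == "C2"]
  expect_equal(d_C1, 0, tolerance = 1e-12)
  expect_equal(d_C2, 2, tolerance = 1e-12)
})

test_that("pair table has the exact cross-run census", {
  ps <- makePatternSet(seed = 71L)
  tab <- patternDistanceMatrix(ps)
  # C(36,2) minus within-run pairs 6 * C(6,2)
  expect_equal(nrow(tab), choose(36L, 2L) - 6L * choose(6L, 2L))
  expect_equal(unname(table(tab$pair_class)[c("same_odor",
                                              "within_category",
                                              "across_category")]),
               c(90L, 90L, 360L), ignore_attr = TRUE)
  expect_true(all(tab$run_i != tab$run_j))
  expect_true(all(tab$distance >= 0 & tab$distance <= 2))
})

test_that("pipeline distances equal a brute-force reimplementation", {
  for (s in 1:5) {
    ps <- makePatternSet(patternGeometry(25L), seed = 80L + s)
    info <- patternInfo(ps)
    mine <- patternDistanceMatrix(ps)
    brute <- bruteDistanceTable(betaMatrix(ps), info$odor, info$category,
                                info$run)
    expect_equal(nrow(mine), nrow(brute))
    key <- function(d) order(d$run_i, d$run_j, d$odor_i, d$odor_j)
    mine <- mine[key(mine), ]; brute <- brute[key(brute), ]
    expect_equal(mine$distance, brute$distance, tolerance = 1e-12)
    expect_identical(mine$pair_class, brute$pair_class)
  }
})

test_that("zero-variance patterns are rejected by name", {
  B <- matrix(rnorm(40L), 10L, 4L)
  B[, 2L] <- 3
  expect_error(odorMVPA:::.distanceTableCore(
    B, odor = c("C1", "C2", "C1", "C2"),
    category = rep("citrus", 4L), run = c(1L, 1L, 2L, 2L)),
    "zero-variance.*C2")
})

test_that("summaries apply the same-odor baseline arithmetic", {
  ps <- makePatternSet(seed = 72L)
  tab <- patternDistanceMatrix(ps)
  sm <- summarizeDistances(tab)
  m <- tapply(tab$distance, tab$pair_class, mean)
  expect_equal(sm$adj_within, m[["within_category"]] - m[["same_odor"]])
  expect_equal(sm$adj_across, m[["across_category"]] - m[["same_odor"]])
  # empty class fails
  expect_error(summarizeDistances(tab[tab$pair_class != "same_odor", ]),
               "empty pair class")
})

test_that("collapsed odor component sends adjusted within to zero", {
  sims <- vapply(seq_len(80L), function(s) {
    truth <- generatePatternGeometry(patternGeometry(100L,
                                                     sigma_odor = 0),
                                     seed = s)
    rp <- generateRunPatterns(truth, 6L, seed = 5000L + s)
    distanceSummaryFromArray(rp, hem200)$adj_within
  }, numeric(1L))
  expect_equal(mean(sims), 0, tolerance = 0.01)
})

test_that("adjusted distances track closed-form geometry over a grid", {
  for (sc in c(0.5, 1)) {
    for (so in c(0, 1)) {
      geom <- patternGeometry(100L, sigma_cat = sc, sigma_odor = so)
      e <- expectedPatternCorrelations(geom)
      sims <- t(vapply(seq_len(60L), function(s) {
        truth <- generatePatternGeometry(geom, seed = 7000L + s)
        rp <- generateRunPatterns(truth, 6L, seed = 9000L + s)
        sm <- distanceSummaryFromArray(rp, hem200)
        c(sm$adj_within, sm$adj_across)
      }, numeric(2L)))
      expect_lt(abs(mean(sims[, 1L]) - (e[["same"]] - e[["within"]])),
                0.03)
      expect_lt(abs(mean(sims[, 2L]) - (e[["same"]] - e[["across"]])),
                0.03)
    }
  }
})

test_that("planted placebo-post effect raises adjusted within there only", {
  geom <- patternGeometry(100L,
                          planted_effects = plantedDrugEffects(1.3))
  cellMean <- function(group, session) {
    mean(vapply(1:60, function(s) {
      truth <- generatePatternGeometry(geom, group = group,
                                       session = session,
                                       seed = 100L * s + (session == "post"))
      rp <- generateRunPatterns(truth, 6L, seed = 77L * s)
      distanceSummaryFromArray(rp, hem200)$adj_within
    }, numeric(1L)))
  }
  pre_p <- cellMean("placebo", "pre")
  post_p <- cellMean("placebo", "post")
  post_d <- cellMean("drug", "post")
  # oracle: closed-form adjusted within = same - within correlation
  e_pre <- expectedPatternCorrelations(geom, "placebo", "pre")
  e_post <- expectedPatternCorrelations(geom, "placebo", "post")
  expect_lt(abs(pre_p - (e_pre[["same"]] - e_pre[["within"]])), 0.02)
  expect_lt(abs(post_p - (e_post[["same"]] - e_post[["within"]])), 0.02)
  expect_lt(abs(post_d - pre_p), 0.02)
  expect_gt(post_p, pre_p + 0.05)
})

test_that("per-run strength averages to the session-level contrast", {
  ps <- makePatternSet(seed = 73L)
  tab <- patternDistanceMatrix(ps)
  st <- categorizationStrength(tab)
  expect_equal(nrow(st), 6L)
  # strong category geometry: positive strength in every run
  expect_true(all(st$strength > 0))
  # weighting identity: each cross-run pair contributes to two runs, so
  # the run average equals the session-level across-minus-within mean
  m <- tapply(tab$distance, tab$pair_class, mean)
  expect_equal(mean(st$strength),
               m[["across_category"]] - m[["within_category"]],
               tolerance = 1e-10)
  # equal within and across distances: zero strength
  tab0 <- data.frame(odor_i = c("C1", "C1"), run_i = c(1L, 1L),
                     odor_j = c("C2", "M1"), run_j = c(2L, 2L),
                     distance = c(0.7, 0.7),
                     pair_class = c("within_category", "across_category"))
  expect_equal(categorizationStrength(tab0)$strength, c(0, 0))
})

test_that("order-effect regression is null-calibrated and guards input", {
  set.seed(74L)
  mkData <- function(n_subj, coupled = FALSE) {
    d <- expand.grid(subject = sprintf("s%02d", seq_len(n_subj)),
                     run = 1:6, stringsAsFactors = FALSE)
    d$rep_percent <- runif(nrow(d), 0, 50)
    d$strength <- rnorm(nrow(d), 0.3, 0.1) +
      if (coupled) -0.004 * d$rep_percent else 0
    d
  }
  ps <- vapply(1:200, function(i) {
    d <- mkData(16L)
    res <- orderEffectRegression(d[, c("subject", "run", "rep_percent")],
                                 d[, c("subject", "run", "strength")])
    res$p
  }, numeric(1L))
  # null: mean r near zero, p roughly uniform
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # planted coupling detected
  hits <- vapply(1:30, function(i) {
    d <- mkData(16L, coupled = TRUE)
    orderEffectRegression(d[, c("subject", "run", "rep_percent")],
                          d[, c("subject", "run", "strength")])$p < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
  # constant repetition percentages: excluded with a log
  d <- mkData(5L)
  d$rep_percent[d$subject == "s01"] <- 25
  expect_message(res <- orderEffectRegression(
    d[, c("subject", "run", "rep_percent")],
    d[, c("subject", "run", "strength")]), "excluded")
  expect_true("s01" %in% res$excluded)
})

test_that("repetition-condition correlations detect planted differences", {
  mkTrials <- function(effect = 0, seed = 1L) {
    set.seed(seed)
    n_per <- 6L
    info <- data.frame(
      trial = seq_len(2L * n_per * 6L),
      odor = rep(defaultOdors, each = 2L * n_per),
      category = rep(unname(defaultCategories[defaultOdors]),
                     each = 2L * n_per),
      catch = FALSE,
      repetition = rep(rep(c("rep", "nonrep"), each = n_per), 6L),
      stringsAsFactors = FALSE)
    base <- matrix(rnorm(6L * 30L), 6L, 30L)
    rep_shift <- matrix(rnorm(6L * 30L), 6L, 30L)
    pat <- t(vapply(seq_len(nrow(info)), function(i) {
      o <- match(info$odor[i], defaultOdors)
      base[o, ] + effect * rep_shift[o, ] *
        (info$repetition[i] == "rep") + rnorm(30L, 0, 0.8)
    }, numeric(30L)))
    list(patterns = pat, info = info, dropped = integer(0L))
  }
  # null: the two correlation types agree on average
  diffs <- vapply(1:60, function(s) {
    r <- repetitionPatternCorrelations(mkTrials(0, s))
    r$rep_rep - r$rep_nonrep
  }, numeric(1L))
  expect_equal(mean(diffs), 0, tolerance = 0.02)
  # planted repetition component: rep-rep exceeds rep-nonrep
  diffs2 <- vapply(1:30, function(s) {
    r <- repetitionPatternCorrelations(mkTrials(1, 100L + s))
    r$rep_rep - r$rep_nonrep
  }, numeric(1L))
  expect_gte(mean(diffs2 > 0.05), 0.8)
  # an odor with a single repetition trial is skipped with a log
  tl <- mkTrials(0, 7L)
  drop <- which(tl$info$odor == "C1" & tl$info$repetition == "rep")[-1L]
  tl$patterns <- tl$patterns[-drop, ]
  tl$info <- tl$info[-drop, ]
  expect_message(r <- repetitionPatternCorrelations(tl), "C1")
  expect_false("C1" %in% r$per_odor$odor)
})

test_that("brain-behaviour correlation behaves at its endpoints", {
  # perfectly monotone increasing: rho = 1
  x <- 1:14
  y <- x^3 + 2
  res <- brainBehaviorChange(x, y, method = "spearman")
  expect_equal(res$estimate, 1)
  # independent deltas: one-tailed p roughly uniform
  set.seed(75L)
  ps <- vapply(1:300, function(i) {
    brainBehaviorChange(rnorm(14L), rnorm(14L), method = "spearman")$p
  }, numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(brainBehaviorChange(rnorm(3L), rnorm(3L)), "four")
})

test_that("planted correlation detection tracks analytic power", {
  # oracle: Fisher-z power for a one-tailed test at alpha = .05, n = 14
  n <- 14L; rho <- 0.5
  z <- atanh(rho) * sqrt(n - 3L)
  analytic <- pnorm(z - qnorm(0.95))
  set.seed(76L)
  hits <- vapply(seq_len(400L), function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    brainBehaviorChange(x, y, method = "pearson")$p < 0.05
  }, logical(1L))
  expect_lt(abs(mean(hits) - analytic), 0.06)
})
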