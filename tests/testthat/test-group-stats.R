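test_that("mixed ANOVA matches the independent oracle on random data", {
  skip_if_not_installed("car")
  cases <- list(
    list(w = list(session = c("pre", "post")), n = c(7L, 5L)),
    list(w = list(session = c("pre", "post"),
                  category = c("within", "across")), n = c(9L, 7L)),
    list(w = list(session = c("pre", "post"),
                  category = c("within", "across"),
                  modality = c("olf", "vis")), n = c(6L, 5L)),
    list(w = list(odor = c("a", "b", "c")), n = c(8L, 6L)),
    list(w = list(w1 = c("p", "q"), w2 = c("x", "y", "z")), n = c(7L, 5L))
  )
  id <- 0L
  for (case in cases) {
    for (rep_i in 1:2) {
      id <- id + 1L
      d <- randomMixedData(case$n, case$w, seed = id)
      mine <- mixedAnova(d, dv = "value", subject = "subject",
                         between = "group", within = names(case$w))
      oracle <- carMixedAnova(d, "value", "subject", "group",
                              names(case$w))
      for (k in seq_len(nrow(mine))) {
        eff <- matchCarEffect(mine$effect[k], "group")
        row <- oracle[oracle$effect == eff, ]
        expect_equal(mine$F[k], row$F, tolerance = 1e-8,
                     label = paste("F for", mine$effect[k]))
        expect_equal(mine$df1[k], row$df1)
        expect_equal(mine$df2[k], row$df2)
        expect_equal(mine$p[k], row$p, tolerance = 1e-8)
      }
    }
  }
})

test_that("GG epsilon matches car and is 1 for two-level factors", {
  skip_if_not_installed("car")
  d <- randomMixedData(c(8L, 6L), list(w1 = c("p", "q"),
                                       w2 = c("x", "y", "z")), seed = 31L)
  mine <- mixedAnova(d, dv = "value", subject = "subject",
                     between = "group", within = c("w1", "w2"))
  # two-level within factor: epsilon identically 1
  expect_equal(mine$eps[mine$effect == "w1"], 1)
  expect_equal(mine$df1_gg[mine$effect == "w1"],
               mine$df1[mine$effect == "w1"])
  # three-level factor: epsilon in (1/(k-1), 1], equal to car's
  cell <- paste(d$w1, d$w2, sep = ".")
  w <- tapply(d$value, list(as.character(d$subject), cell), mean)
  idata <- do.call(rbind, strsplit(colnames(w), "\\."))
  idata <- data.frame(w1 = factor(idata[, 1L]),
                      w2 = factor(idata[, 2L]))
  g <- factor(tapply(as.character(d$group), as.character(d$subject),
                     function(x) x[1L])[rownames(w)])
  s <- suppressWarnings(summary(car::Anova(
    stats::lm(w ~ g, contrasts = list(g = "contr.sum")),
    idata = idata, idesign = ~ w1 * w2, type = 3),
    multivariate = FALSE))
  eps_car <- s$pval.adjustments["w2", "GG eps"]
  eps_mine <- mine$eps[mine$effect == "w2"]
  expect_equal(eps_mine, unname(eps_car), tolerance = 1e-8)
  expect_gt(eps_mine, 1 / 2)
  expect_lte(eps_mine, 1)
})

test_that("hand-computed balanced two-way mixed case agrees", {
  # balanced 2 groups x 3 subjects x 2 sessions; classical SS by hand
  vals <- matrix(c(4, 6, 5, 7, 3, 4,      # group a: pre, post per subject
                   8, 9, 6, 5, 7, 9), nrow = 2L)
  d <- data.frame(subject = rep(sprintf("s%d", 1:6), each = 2L),
                  group = rep(c("a", "b"), each = 6L),
                  session = rep(c("pre", "post"), 6L),
                  value = as.vector(vals))
  mine <- mixedAnova(d, dv = "value", subject = "subject",
                     between = "group", within = "session")
  subj_means <- tapply(d$value, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, function(x) x[1L])
  grand <- mean(subj_means)
  grp_means <- tapply(subj_means, grp_of, mean)
  ss_group <- 2 * 3 * sum((grp_means - grand)^2)
  ss_subj <- 2 * sum((subj_means - grp_means[grp_of])^2)
  F_group <- (ss_group / 1) / (ss_subj / 4)
  expect_equal(mine$F[mine$effect == "group"], F_group,
               tolerance = 1e-10)
  # session effect from per-subject differences
  diffs <- tapply(d$value, d$subject,
                  function(x) x[1L] - x[2L])    # pre - post
  grp_diff_means <- tapply(diffs, grp_of, mean)
  ss_sess <- 3 * 2 * mean(grp_diff_means)^2 / 2 * 2
  # classical: SS_session = n_total/2 * (mean diff / ... ) — compute via
  # contrast scores z = (pre - post)/sqrt(2)
  z <- diffs / sqrt(2)
  zg <- tapply(z, grp_of, mean)
  ss_sess <- 6 * mean(zg)^2
  ss_sxg <- 3 * sum((zg - mean(zg))^2)
  ss_err <- sum((z - zg[grp_of])^2)
  expect_equal(mine$F[mine$effect == "session"],
               (ss_sess / 1) / (ss_err / 4), tolerance = 1e-10)
  expect_equal(mine$F[mine$effect == "group:session"],
               (ss_sxg / 1) / (ss_err / 4), tolerance = 1e-10)
})

test_that("degenerate and pure-within designs are handled", {
  # all equal values: F = 0 everywhere
  d <- randomMixedData(c(4L, 4L), list(session = c("pre", "post")),
                       seed = 32L)
  d$value <- 5
  tab <- mixedAnova(d, dv = "value", subject = "subject",
                    between = "group", within = "session")
  expect_true(all(tab$F == 0))
  # pure repeated measures (no between factor)
  d2 <- randomMixedData(c(6L, 0L), list(odor = letters[1:4]), seed = 33L)
  tab2 <- mixedAnova(d2, dv = "value", subject = "subject",
                     within = "odor")
  expect_equal(tab2$effect, "odor")
  expect_equal(tab2$df1, 3L)
  expect_equal(tab2$df2, 15L)
  # incomplete cells named
  d3 <- randomMixedData(c(4L, 3L), list(session = c("pre", "post")),
                        seed = 34L)
  d3 <- d3[-1L, ]
  expect_error(mixedAnova(d3, dv = "value", subject = "subject",
                          between = "group", within = "session"),
               "incomplete within-subject")
})

test_that("interaction p-values are uniform under the null", {
  set.seed(35L)
  ps <- vapply(seq_len(400L), function(i) {
    d <- randomMixedData(c(9L, 7L), list(session = c("pre", "post"),
                                         category = c("w", "a")),
                         seed = 10000L + i)
    tab <- mixedAnova(d, dv = "value", subject = "subject",
                      between = "group", within = c("session",
                                                    "category"))
    tab$p[tab$effect == "group:session:category"]
  }, numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("simple effects recompute error terms within the slice", {
  d <- randomMixedData(c(8L, 6L), list(session = c("pre", "post"),
                                       category = c("w", "a")),
                       seed = 36L)
  se <- simpleEffects(d, dv = "value", subject = "subject",
                      between = "group", within = c("session", "category"),
                      at = c(session = "pre"))
  ref <- mixedAnova(d[d$session == "pre", ], dv = "value",
                    subject = "subject", between = "group",
                    within = "category")
  expect_equal(se, ref)
  # conditioning on a single-level factor reproduces the full analysis
  d$block <- "one"
  se2 <- simpleEffects(d, dv = "value", subject = "subject",
                       between = "group", within = c("session",
                                                     "category"),
                       at = c(block = "one"))
  expect_equal(se2, mixedAnova(d, dv = "value", subject = "subject",
                               between = "group",
                               within = c("session", "category")))
  expect_error(simpleEffects(d, dv = "value", subject = "subject",
                             within = "session", at = c(session = "pre")),
               "no factor")
  # planted effect only at pre is found there and not at post
  hits <- vapply(1:30, function(s) {
    d2 <- randomMixedData(c(9L, 7L), list(session = c("pre", "post"),
                                          category = c("w", "a")),
                          seed = 500L + s)
    d2$value <- d2$value +
      ifelse(d2$session == "pre" & d2$category == "w", 1.4, 0)
    p_pre <- simpleEffects(d2, dv = "value", subject = "subject",
                           between = "group",
                           within = c("session", "category"),
                           at = c(session = "pre"))
    p_post <- simpleEffects(d2, dv = "value", subject = "subject",
                            between = "group",
                            within = c("session", "category"),
                            at = c(session = "post"))
    c(p_pre$p[p_pre$effect == "category"] < 0.05,
      p_post$p[p_post$effect == "category"] < 0.05)
  }, logical(2L))
  expect_gte(mean(hits[1L, ]), 0.8)
  expect_lt(mean(hits[2L, ]), 0.3)
})

test_that("t tests agree with the reference distribution", {
  set.seed(37L)
  # symmetric values about the reference: one-tailed p near 0.5
  x <- c(rnorm(20L), -rnorm(20L))
  res <- tTest(x, mu = 0, tail = "greater")
  expect_equal(res$p, 0.5, tolerance = 0.2)
  # paired identical vectors error on zero variance (documented)
  expect_error(tTest(1:5, 1:5), "zero variance")
  # agreement with the closed-form t CDF at random inputs
  for (i in 1:20) {
    v <- rnorm(sample(5:30, 1L), mean = runif(1L, -1, 1))
    res <- tTest(v, mu = 0, tail = "two")
    tt <- mean(v) / (sd(v) / sqrt(length(v)))
    expect_equal(res$t, tt, tolerance = 1e-10)
    expect_equal(res$p, 2 * pt(-abs(tt), length(v) - 1L),
                 tolerance = 1e-12)
  }
})

test_that("correlation tests distinguish linear and monotone structure", {
  x <- 1:20
  expect_equal(correlationTest(x, 2 * x + 3, "pearson")$estimate, 1)
  y <- exp(x / 4)
  expect_equal(correlationTest(x, y, "spearman")$estimate, 1)
  expect_lt(correlationTest(x, y, "pearson")$estimate, 1)
  expect_error(correlationTest(x, rep(1, 20L)), "constant")
  expect_error(correlationTest(1:3, 1:3), "four")
  # one-tailed p uniform under the null
  set.seed(38L)
  ps <- vapply(seq_len(500L), function(i) {
    correlationTest(rnorm(14L), rnorm(14L), "pearson", "greater")$p
  }, numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
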