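## Mixed between/within factorial ANOVA via the classical univariate
## (orthonormal-contrast projection) approach.
##
## For each within-subject effect, the subject x cell response matrix is
## projected onto an orthonormal contrast basis spanning that effect; a
## multivariate linear model on the between-subject design (sum-to-zero
## coding, Type III hypothesis sums of squares) then yields the within
## effect (intercept block) and its interaction with the between factor
## (group block), with error taken from the residual cross-products — the
## factor-by-subject(-within-group) stratum. Between-subject effects come
## from the same machinery applied to the cell-mean (unit) projection.
## Greenhouse-Geisser epsilon is computed from the pooled covariance of the
## contrast scores; for two-level factors the projection is univariate and
## epsilon is identically 1.

## orthonormal contrasts for a k-level factor (k x (k-1)), orthogonal to
## the unit vector
.orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), "/")
}

## wide subject x within-cell matrix from long data; checks completeness
.wideWithin <- function(data, dv, subject, within) {
  subj <- as.character(data[[subject]])
  subjects <- unique(subj)
  if (length(within) == 0L) {
    agg <- tapply(data[[dv]], subj, mean)
    return(list(Y = matrix(agg[subjects], ncol = 1L,
                           dimnames = list(subjects, "value")),
                levels = list(), cells = NULL))
  }
  lev <- lapply(within, function(w) {
    x <- data[[w]]
    if (is.factor(x)) levels(x) else unique(as.character(x))
  })
  names(lev) <- within
  cells <- expand.grid(lev, stringsAsFactors = FALSE)  # first factor fastest
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  data_key <- do.call(paste, c(lapply(within, function(w)
    as.character(data[[w]])), sep = "\r"))
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, NULL))
  for (i in seq_along(cell_key)) {
    hit <- data_key == cell_key[i]
    vals <- tapply(data[[dv]][hit], subj[hit], mean)
    Y[names(vals), i] <- vals
  }
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1L, ]
    stop("incomplete within-subject design: subject ",
         rownames(Y)[bad[1L]], " is missing cell ",
         paste(unlist(cells[bad[2L], ]), collapse = "/"))
  }
  list(Y = Y, levels = lev, cells = cells)
}

## Type III hypothesis SS for a coefficient row block of a multivariate lm
.typeIIIss <- function(B, XtXinv, rows) {
  BL <- B[rows, , drop = FALSE]
  M <- XtXinv[rows, rows, drop = FALSE]
  sum(diag(crossprod(BL, solve(M, BL))))
}

#' Mixed between/within factorial ANOVA
#'
#' Fits the classical mixed-design ANOVA with one (optional) between-subject
#' factor and any number of fully-crossed within-subject factors, testing
#' between effects against the subject-within-group mean square and each
#' within effect (and its group interaction) against its factor-by-subject
#' stratum. Unequal group sizes are handled with Type III (unweighted-means)
#' hypothesis sums of squares. Greenhouse-Geisser sphericity correction is
#' reported for every within stratum (epsilon = 1 when the stratum is
#' one-dimensional, i.e. all involved factors have two levels).
#'
#' @param data long-format data.frame
#' @param dv name of the numeric response column
#' @param subject name of the subject identifier column
#' @param between optional name of a single between-subject factor column
#' @param within character vector of within-subject factor columns
#' @return data.frame of class `AnovaTable`: `effect`, `df1`, `df2`, `F`,
#'   `p`, `eps` (GG), `df1_gg`, `df2_gg`, `p_gg`
#' @export
mixedAnova <- function(data, dv = "value", subject = "subject",
                       between = NULL, within = character(0L)) {
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data), length(between) <= 1L,
            all(within %in% names(data)))
  if (!is.null(between)) stopifnot(between %in% names(data))
  wide <- .wideWithin(data, dv, subject, within)
  Y <- wide$Y
  n <- nrow(Y)
  ## between design, sum-to-zero coding
  if (!is.null(between)) {
    gmap <- tapply(as.character(data[[between]]),
                   as.character(data[[subject]]),
                   function(x) {
                     u <- unique(x)
                     if (length(u) > 1L)
                       stop("subject with more than one level of ", between)
                     u
                   })
    gvec <- factor(gmap[rownames(Y)])
    if (nlevels(gvec) < 2L) { between <- NULL }
  }
  if (!is.null(between)) {
    if (any(table(gvec) < 2L)) {
      stop("need at least two subjects per level of ", between)
    }
    X <- stats::model.matrix(~ g, data = data.frame(g = gvec),
                             contrasts.arg = list(g = "contr.sum"))
  } else {
    X <- matrix(1, n, 1L)
  }
  g <- ncol(X)
  if (n <= g) stop("not enough subjects for the between-subject design")
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  lev <- wide$levels
  k <- vapply(lev, length, integer(1L))
  rows_int <- 1L
  rows_grp <- if (g > 1L) 2L:g else integer(0L)

  subsets <- list(integer(0L))
  if (length(within) > 0L) {
    for (j in seq_along(within)) {
      subsets <- c(subsets, utils::combn(seq_along(within), j,
                                         simplify = FALSE))
    }
  }
  rows <- list()
  for (e in subsets) {
    ## Kronecker over within factors, first factor fastest => last outermost
    Cmats <- lapply(seq_along(within), function(j) {
      if (j %in% e) .orthonormalContrasts(k[j])
      else matrix(1 / sqrt(k[j]), k[j], 1L)
    })
    Ctot <- matrix(1, 1L, 1L)
    for (j in rev(seq_along(within))) Ctot <- Ctot %x% Cmats[[j]]
    if (length(within) == 0L) Ctot <- matrix(1, 1L, 1L)
    Z <- Y %*% Ctot
    ce <- ncol(Z)
    B <- XtXinv %*% crossprod(X, Z)
    E <- Z - X %*% B
    SSPE <- crossprod(E)
    SSE <- sum(diag(SSPE))
    df_e <- (n - g) * ce
    S <- SSPE / (n - g)
    eps <- if (ce > 1L && sum(S * S) > 0)
      sum(diag(S))^2 / (ce * sum(S * S)) else 1
    ename <- paste(within[e], collapse = ":")
    add_effect <- function(label, r) {
      if (length(r) == 0L) return(NULL)
      SSH <- .typeIIIss(B, XtXinv, r)
      df_h <- length(r) * ce
      Fv <- if (SSH <= .Machine$double.eps * max(1, sum(Z^2))) 0
      else (SSH / df_h) / (SSE / df_e)
      data.frame(effect = label, df1 = df_h, df2 = df_e, F = Fv,
                 p = stats::pf(Fv, df_h, df_e, lower.tail = FALSE),
                 eps = eps, df1_gg = df_h * eps, df2_gg = df_e * eps,
                 p_gg = stats::pf(Fv, df_h * eps, df_e * eps,
                                  lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }
    if (length(e) == 0L) {
      ## between-subject stratum: group effect against subject(group)
      if (g > 1L) rows <- c(rows, list(add_effect(between, rows_grp)))
    } else {
      rows <- c(rows, list(add_effect(ename, rows_int)))
      if (g > 1L) rows <- c(rows, list(
        add_effect(paste(between, ename, sep = ":"), rows_grp)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("AnovaTable", class(out))
  out
}

#' Simple-effects analysis at one level of a conditioning factor
#'
#' Slices the data at a single level of one factor and re-runs the mixed
#' ANOVA on the remaining factors, recomputing the error terms within the
#' slice (the conventional follow-up to a significant interaction).
#'
#' @inheritParams mixedAnova
#' @param at named length-1 character vector: `c(factor = "level")`
#' @return an `AnovaTable` for the slice
#' @export
simpleEffects <- function(data, dv = "value", subject = "subject",
                          between = NULL, within = character(0L), at) {
  stopifnot(length(at) == 1L, !is.null(names(at)))
  fac <- names(at)
  if (!fac %in% names(data)) stop("conditioning factor ", fac, " not found")
  keep <- as.character(data[[fac]]) == at[[1L]]
  if (!any(keep)) stop("conditioning level ", at[[1L]], " not present in ",
                       fac)
  slice <- data[keep, , drop = FALSE]
  within2 <- setdiff(within, fac)
  between2 <- if (!is.null(between) && between == fac) NULL else between
  if (length(within2) == 0L && is.null(between2)) {
    stop("slice leaves no factor to test")
  }
  mixedAnova(slice, dv = dv, subject = subject, between = between2,
             within = within2)
}

#' One-sample or paired t test with explicit tail
#'
#' @param x numeric vector
#' @param y optional paired vector
#' @param mu reference value for the one-sample test (default 0)
#' @param tail `"two"`, `"greater"` or `"less"`
#' @return list: `t`, `df`, `p`, `estimate` (mean or mean difference)
#' @export
tTest <- function(x, y = NULL, mu = 0, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  d <- if (is.null(y)) x else { stopifnot(length(x) == length(y)); x - y }
  if (length(d) < 2L) stop("need at least two observations")
  if (stats::sd(d) == 0) stop("zero variance: t statistic undefined")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  if (is.null(y)) {
    ht <- stats::t.test(x, mu = mu, alternative = alt)
  } else {
    ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate)[1L])
}

#' Correlation test with explicit tail
#'
#' @param x,y numeric vectors
#' @param method `"pearson"` or `"spearman"` (tie midranks, tie-corrected
#'   approximate p)
#' @param tail `"two"`, `"greater"` or `"less"`
#' @return list: `estimate` (r or rho), `p`, `n`, `method`
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman"),
                            tail = c("two", "greater", "less")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least four paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  ht <- suppressWarnings(stats::cor.test(
    x, y, method = method, alternative = alt,
    exact = if (method == "spearman") FALSE else NULL))
  list(estimate = unname(ht$estimate), p = ht$p.value, n = length(x),
       method = method)
}
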