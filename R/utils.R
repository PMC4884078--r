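## Small shared numerical helpers.

#' Trapezoidal integral of sampled values
#'
#' @param x sample locations (strictly increasing)
#' @param y sampled values
#' @return numeric scalar, the trapezoid-rule integral
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Discrete-cosine drift basis
#'
#' Returns the DCT-II basis columns whose period exceeds `cutoff` seconds,
#' i.e. the low-frequency nuisance set used for high-pass filtering inside
#' the GLM. The constant term is excluded (the design carries its own
#' intercept).
#'
#' @param n_scans number of scans in the run
#' @param tr repetition time in seconds
#' @param cutoff high-pass cutoff period in seconds (default 128)
#' @return matrix with `n_scans` rows; zero columns if the run is shorter
#'   than the cutoff period
#' @export
dctBasis <- function(n_scans, tr, cutoff = 128) {
  stopifnot(n_scans >= 1L, tr > 0, cutoff > 0)
  ## component k has period 2 * n_scans * tr / k; keep periods > cutoff
  k_max <- floor(2 * n_scans * tr / cutoff)
  if (k_max < 1L) {
    return(matrix(numeric(0L), nrow = n_scans, ncol = 0L))
  }
  t_idx <- seq_len(n_scans) - 0.5
  X <- vapply(seq_len(k_max), function(k) {
    sqrt(2 / n_scans) * cos(pi * k * t_idx / n_scans)
  }, numeric(n_scans))
  colnames(X) <- paste0("drift", seq_len(k_max))
  X
}

## z-score a vector; errors on zero variance unless allow_constant
.zscore <- function(x, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score ", what, ": zero or non-finite variance")
  }
  (x - mean(x)) / s
}

## deterministic per-stage seed derivation from a global seed; keeps values
## in 32-bit integer range
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

## run code under a local RNG state, restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
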