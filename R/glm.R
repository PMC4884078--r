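## Event-related GLM with canonical HRF, sniff nuisance, discrete-cosine
## high-pass filtering and AR(1) prewhitening.
##
## Regressors of interest are stick (delta) trains at stimulus onsets
## convolved with a double-gamma canonical haemodynamic response. Nuisance
## terms: one catch-onset regressor, motion series, one inhalation-volume
## regressor orthogonalised against the condition columns, low-frequency
## cosine drift terms (cutoff period 128 s) and an intercept. Estimation is
## two-pass: OLS, pooled lag-1 residual autocorrelation, AR(1) whitening,
## refit.

#' Canonical HRF specification
#'
#' Double-gamma parameterisation: response peak delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6, 32-s kernel.
#'
#' @param peak_delay,undershoot_delay gamma shape parameters (s)
#' @param peak_disp,undershoot_disp gamma dispersions (s)
#' @param undershoot_ratio relative undershoot amplitude
#' @param length_s kernel support in seconds
#' @return list of class `HrfSpec`
#' @export
hrfSpec <- function(peak_delay = 6, undershoot_delay = 16,
                    peak_disp = 1, undershoot_disp = 1,
                    undershoot_ratio = 1 / 6, length_s = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, undershoot_ratio >= 0, length_s > 0)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 undershoot_ratio = undershoot_ratio, length_s = length_s),
            class = "HrfSpec")
}

#' Sample the canonical haemodynamic response kernel
#'
#' @param spec an [hrfSpec()]
#' @param dt sampling interval in seconds
#' @return numeric vector of kernel samples on `[0, length_s]`
#' @export
canonicalHrf <- function(spec = hrfSpec(), dt = 0.1) {
  stopifnot(dt > 0)
  t <- seq(0, spec$length_s, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     scale = spec$peak_disp) -
    spec$undershoot_ratio *
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                  scale = spec$undershoot_disp)
  h
}

## convolve an onset train (optionally amplitude-modulated) with the HRF on
## a microtime grid, then sample at scan acquisition times
.hrfRegressor <- function(onsets, amplitudes = NULL, hrf = hrfSpec(),
                          tr, n_scans, dt = 0.1) {
  if (length(onsets) == 0L) return(numeric(n_scans))
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  n_fine <- ceiling((n_scans * tr + hrf$length_s) / dt) + 1L
  train <- numeric(n_fine)
  idx <- round(onsets / dt) + 1L
  keep <- idx >= 1L & idx <= n_fine
  train[idx[keep]] <- train[idx[keep]] + amplitudes[keep]
  kernel <- canonicalHrf(hrf, dt)
  conv <- stats::convolve(train, rev(kernel), type = "open")[seq_len(n_fine)]
  scan_idx <- round((seq_len(n_scans) - 1L) * tr / dt) + 1L
  conv[scan_idx]
}

#' Build the run-level design matrix
#'
#' Columns: one HRF-convolved stick regressor per odor condition, a
#' catch-onset nuisance regressor, motion nuisance columns, one
#' inhalation-volume regressor orthogonalised against the condition block,
#' cosine drift terms below the high-pass cutoff, and an intercept.
#' Catch trials contribute only to the catch regressor, never to the
#' condition regressors.
#'
#' @param events event-table rows for one run
#' @param sniff optional per-trial sniff features (data.frame with a
#'   `volume` column aligned to `events` rows) or NULL to omit the sniff
#'   regressor (visual modality)
#' @param motion optional matrix of motion nuisance series (n_scans rows)
#' @param hrf an [hrfSpec()]
#' @param tr repetition time (s)
#' @param n_scans scans in the run
#' @param highpass_cutoff drift cutoff period in seconds (default 128)
#' @param conditions condition labels; default the sorted odor labels
#' @return list of class `DesignMatrix`: `X` (n_scans x p), `condition_cols`,
#'   `col_class` (condition/catch/motion/sniff/drift/intercept)
#' @export
buildDesignMatrix <- function(events, sniff = NULL, motion = NULL,
                              hrf = hrfSpec(), tr = 2.3, n_scans,
                              highpass_cutoff = 128, conditions = NULL) {
  stopifnot(length(unique(events$run)) == 1L, n_scans >= 1L)
  if (any(events$onset >= n_scans * tr)) {
    stop("event onsets extend beyond the sampled run")
  }
  if (is.null(conditions)) conditions <- sort(unique(events$odor))
  noncatch <- !events$catch
  Xcond <- vapply(conditions, function(cond) {
    .hrfRegressor(events$onset[noncatch & events$odor == cond],
                  hrf = hrf, tr = tr, n_scans = n_scans)
  }, numeric(n_scans))
  cols <- list(Xcond)
  classes <- rep("condition", length(conditions))
  nm <- conditions
  if (any(events$catch)) {
    cols <- c(cols, list(.hrfRegressor(events$onset[events$catch],
                                       hrf = hrf, tr = tr,
                                       n_scans = n_scans)))
    classes <- c(classes, "catch"); nm <- c(nm, "catch")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_scans)
    cols <- c(cols, list(motion))
    classes <- c(classes, rep("motion", ncol(motion)))
    nm <- c(nm, paste0("motion", seq_len(ncol(motion))))
  }
  if (!is.null(sniff)) {
    vol <- sniff$volume
    stopifnot(length(vol) == nrow(events))
    sn <- .hrfRegressor(events$onset, amplitudes = vol, hrf = hrf,
                        tr = tr, n_scans = n_scans)
    ## orthogonalise against the span of the condition columns
    qr_c <- qr(Xcond)
    sn <- sn - qr.fitted(qr_c, sn)
    cols <- c(cols, list(sn))
    classes <- c(classes, "sniff"); nm <- c(nm, "sniff_volume")
  }
  drift <- dctBasis(n_scans, tr, highpass_cutoff)
  if (ncol(drift) > 0L) {
    cols <- c(cols, list(drift))
    classes <- c(classes, rep("drift", ncol(drift)))
    nm <- c(nm, colnames(drift))
  }
  cols <- c(cols, list(rep(1, n_scans)))
  classes <- c(classes, "intercept"); nm <- c(nm, "intercept")
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- nm[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, condition_cols = match(conditions, nm),
                 col_class = classes, conditions = conditions,
                 tr = tr),
            class = "DesignMatrix")
}

## Map an observed pooled lag-1 residual autocorrelation back to the AR(1)
## coefficient of the noise: under noise covariance Sigma(rho) the residual
## statistic has expectation subdiag(M Sigma M) / tr(M Sigma M) with
## M = I - H the residual projector; solve for rho by root finding.
.debiasAr1 <- function(stat, qrX, n) {
  if (stat == 0) return(0)
  implied <- function(rho) {
    Sig <- stats::toeplitz(rho^(0:(n - 1L)))
    MS <- Sig - qr.fitted(qrX, Sig)          # M Sigma
    MSM <- t(MS) - qr.fitted(qrX, t(MS))     # M Sigma M
    sum(MSM[cbind(2:n, 1:(n - 1L))]) / sum(diag(MSM))
  }
  lo <- -0.95; hi <- 0.95
  f_lo <- implied(lo) - stat; f_hi <- implied(hi) - stat
  if (f_lo * f_hi > 0) return(stat)          # outside invertible range
  stats::uniroot(function(r) implied(r) - stat, c(lo, hi),
                 tol = 1e-4)$root
}

## AR(1) whitening transform applied to rows of a matrix (or vector)
.ar1Whiten <- function(M, rho) {
  M <- as.matrix(M)
  n <- nrow(M)
  W <- rbind(M[1L, , drop = FALSE] * sqrt(1 - rho^2),
             M[-1L, , drop = FALSE] - rho * M[-n, , drop = FALSE])
  W
}

#' Fit the run-level GLM with AR(1) prewhitening
#'
#' Two-pass estimation: ordinary least squares; AR(1) coefficient estimated
#' from the lag-1 autocorrelation of residuals pooled across voxels; rows of
#' data and design whitened by the AR(1) inverse square-root transform;
#' refit.
#'
#' @param timeseries n_scans x n_voxels matrix
#' @param design a [buildDesignMatrix()] result
#' @return list of class `GlmFit`: `beta` (regressor x voxel), `sigma2`
#'   per-voxel residual variance, `rho` pooled AR(1) estimate, `df`
#'   residual degrees of freedom, `design`
#' @export
fitGlm <- function(timeseries, design) {
  Y <- as.matrix(timeseries)
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  if (!all(is.finite(Y))) stop("non-finite values in time series")
  qr1 <- qr(X)
  res <- qr.resid(qr1, Y)
  num <- sum(res[-1L, ] * res[-nrow(res), ])
  den <- sum(res^2)
  stat <- if (den > 0) num / den else 0
  ## the OLS residual autocorrelation is biased towards zero by the
  ## projection (drift columns absorb slow noise); invert the mapping
  ## rho -> E[lag-1 residual autocorrelation] under this design
  rho <- .debiasAr1(stat, qr1, nrow(Y))
  rho <- max(min(rho, 0.99), -0.99)
  Xw <- .ar1Whiten(X, rho)
  Yw <- .ar1Whiten(Y, rho)
  qr2 <- qr(Xw)
  beta <- qr.coef(qr2, Yw)
  resw <- qr.resid(qr2, Yw)
  df <- nrow(Y) - ncol(X)
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = colSums(resw^2) / df, rho = rho,
                 df = df, residuals_white = resw, design = design),
            class = "GlmFit")
}

#' Extract per-trial sniff features
#'
#' Smooths the run's airflow trace with a moving average, z-scores it
#' (mean 0, sd 1 per run), then parses the cued inhalation after each trial
#' onset: the first flow-positive excursion beginning within `onset_tol`
#' seconds of the cue, ending at the first zero crossing. Features are the
#' peak flow, duration and (trapezoidal) volume of that bout on the scaled
#' trace.
#'
#' @param trace a `SniffTrace` (list with `time`, `flow`, `sampling_rate`)
#' @param events event-table rows for the run
#' @param smooth_window moving-average window in seconds (default 0.25)
#' @param onset_tol seconds after cue within which the inhalation must
#'   start (default 1)
#' @param scale z-score the smoothed trace per run (default TRUE; disable
#'   only for fixture checks against generator truth)
#' @return data.frame of class `SniffFeatures`: trial, odor, peak,
#'   duration, volume
#' @export
extractSniffFeatures <- function(trace, events, smooth_window = 0.25,
                                 onset_tol = 1, scale = TRUE) {
  fs <- trace$sampling_rate
  flow <- trace$flow
  if (stats::sd(flow) == 0) {
    stop("flat respiration trace (zero variance): dead sensor?")
  }
  w <- max(1L, round(smooth_window * fs))
  if (w > 1L) {
    flow <- as.numeric(stats::filter(flow, rep(1 / w, w), sides = 2))
    flow[is.na(flow)] <- 0
  }
  if (scale) flow <- .zscore(flow, "respiration trace")
  soa <- if (nrow(events) > 1L) min(diff(sort(events$onset))) else
    max(trace$time) - max(events$onset)
  out <- lapply(seq_len(nrow(events)), function(i) {
    on <- events$onset[i]
    win <- which(trace$time >= on & trace$time < on + soa)
    f <- flow[win]
    pos <- which(f > 0)
    start <- pos[pos <= round(onset_tol * fs) + 1L][1L]
    if (is.na(start)) {
      return(data.frame(trial = events$trial[i], odor = events$odor[i],
                        peak = NA_real_, duration = NA_real_,
                        volume = NA_real_))
    }
    zc <- which(f[start:length(f)] <= 0)[1L]
    end <- if (is.na(zc)) length(f) else start + zc - 2L
    seg <- start:end
    data.frame(trial = events$trial[i], odor = events$odor[i],
               peak = max(f[seg]),
               duration = length(seg) / fs,
               volume = if (length(seg) >= 2L)
                 trapz(trace$time[win][seg], f[seg]) else 0)
  })
  out <- do.call(rbind, out)
  class(out) <- c("SniffFeatures", class(out))
  out
}

#' Repeated-measures check for odor-dependent sniff parameters
#'
#' Tests each inhalation feature for systematic differences across odors
#' with a repeated-measures ANOVA (Greenhouse-Geisser corrected), the
#' standard screen for sniff confounds before pattern analysis. A feature
#' that differs across odors should be carried into the GLM as a nuisance
#' regressor.
#'
#' @param features data.frame with columns `subject`, `odor` and one or
#'   more feature columns (e.g. `peak`, `duration`, `volume`); trial-level
#'   rows are averaged per subject x odor first
#' @param feature_cols feature columns to test
#' @return data.frame: feature, F, df1, df2 (GG-corrected), p
#' @export
sniffConfoundCheck <- function(features,
                               feature_cols = c("peak", "duration",
                                                "volume")) {
  stopifnot(all(c("subject", "odor") %in% names(features)))
  if (length(unique(features$odor)) < 2L) {
    stop("need at least two odors to test odor differences")
  }
  if (length(unique(features$subject)) < 2L) {
    stop("need at least two subjects for a repeated-measures test")
  }
  out <- lapply(feature_cols, function(fc) {
    cell <- stats::aggregate(features[[fc]],
                             by = list(subject = features$subject,
                                       odor = features$odor),
                             FUN = mean, na.rm = TRUE)
    names(cell)[3L] <- "value"
    if (anyNA(cell$value)) stop("missing cells for feature ", fc)
    tab <- mixedAnova(cell, dv = "value", subject = "subject",
                      within = "odor")
    row <- tab[tab$effect == "odor", ]
    data.frame(feature = fc, F = row$F, df1 = row$df1_gg,
               df2 = row$df2_gg, p = row$p_gg)
  })
  do.call(rbind, out)
}
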