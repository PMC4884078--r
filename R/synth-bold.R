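## Forward BOLD model: stick trains convolved with the canonical HRF,
## weighted by the planted voxel patterns, plus sniff-coupled nuisance,
## low-frequency drift and AR(1) noise, sampled at the TR.

#' BOLD noise configuration
#'
#' @param ar1_rho lag-1 autocorrelation of the additive noise
#' @param sigma_noise innovation scale of the AR(1) noise
#' @param drift_amplitude amplitude of random low-frequency cosine drift
#' @param sniff_gain coupling gain of the inhalation-volume train
#'   (convolved with the HRF, added uniformly to all voxels)
#' @return list of class `BoldNoise`
#' @export
boldNoise <- function(ar1_rho = 0.3, sigma_noise = 1,
                      drift_amplitude = 0.5, sniff_gain = 0.5) {
  stopifnot(abs(ar1_rho) < 1, sigma_noise >= 0, drift_amplitude >= 0)
  structure(list(ar1_rho = ar1_rho, sigma_noise = sigma_noise,
                 drift_amplitude = drift_amplitude,
                 sniff_gain = sniff_gain),
            class = "BoldNoise")
}

#' Synthesize a voxel time series for one run
#'
#' @param events event-table rows for one run
#' @param run_beta odor x voxel matrix of true run-level responses (catch
#'   trials drive their odor's regressor plus, implicitly, the catch
#'   nuisance shape; here catch trials evoke the same odor response)
#' @param noise a [boldNoise()]
#' @param sniff_truth optional per-trial data.frame with `onset` and
#'   `volume` (generator ground truth) driving the sniff-coupled nuisance
#' @param hrf an [hrfSpec()]
#' @param tr repetition time (s)
#' @param n_scans scans in the run
#' @param seed optional integer seed
#' @return n_scans x n_voxels matrix
#' @export
synthesizeBold <- function(events, run_beta, noise = boldNoise(),
                           sniff_truth = NULL, hrf = hrfSpec(), tr = 2.3,
                           n_scans = 208L, seed = NULL) {
  stopifnot(all(events$odor %in% rownames(run_beta)))
  .withSeed(seed, {
    nv <- ncol(run_beta)
    Y <- matrix(0, n_scans, nv)
    for (o in rownames(run_beta)) {
      reg <- .hrfRegressor(events$onset[events$odor == o & !events$catch],
                           hrf = hrf, tr = tr, n_scans = n_scans)
      Y <- Y + outer(reg, run_beta[o, ])
    }
    if (any(events$catch)) {
      ## catch trials evoke the mean odor response plus the decision/probe
      ## process; modelled as one voxel-wise amplitude so the GLM's single
      ## catch nuisance regressor represents them exactly
      reg <- .hrfRegressor(events$onset[events$catch], hrf = hrf, tr = tr,
                           n_scans = n_scans)
      Y <- Y + outer(reg, colMeans(run_beta))
    }
    if (!is.null(sniff_truth) && noise$sniff_gain != 0) {
      sreg <- .hrfRegressor(sniff_truth$onset,
                            amplitudes = sniff_truth$volume,
                            hrf = hrf, tr = tr, n_scans = n_scans)
      Y <- Y + noise$sniff_gain * sreg
    }
    if (noise$drift_amplitude > 0) {
      t_sc <- (seq_len(n_scans) - 1L) * tr
      for (k in 1:3) {
        Y <- Y + noise$drift_amplitude * stats::rnorm(1L) *
          cos(2 * pi * t_sc / (n_scans * tr) * k / 2 +
                stats::runif(1L, 0, 2 * pi))
      }
    }
    if (noise$sigma_noise > 0) {
      innov <- matrix(stats::rnorm(n_scans * nv, sd = noise$sigma_noise),
                      n_scans, nv)
      if (noise$ar1_rho != 0) {
        innov <- apply(innov, 2L, function(w)
          as.numeric(stats::filter(w, noise$ar1_rho, method = "recursive")))
      }
      Y <- Y + innov
    }
    Y
  })
}
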