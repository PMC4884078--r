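## Respiration synthesis: cued inhalations on a resting-breathing baseline.
##
## Each trial elicits one cued inhalation starting at stimulus onset. The
## default inhalation waveform is a gamma-shaped flow curve (smooth, single
## peak, analytically integrable by quadrature); a triangular waveform is
## available because its peak/duration/volume are exact by elementary
## geometry, which makes it the natural fixture for feature-extraction
## tests. Per-trial ground truth (peak flow, duration, volume) is stored
## alongside the trace.

#' Sniff waveform model
#'
#' @param waveform `"gamma"` (default) or `"triangular"`
#' @param peak_flow_mean,peak_flow_sd inhalation peak flow, arbitrary units
#' @param duration_mean,duration_sd inhalation duration, seconds
#' @param sampling_rate trace sampling rate, Hz (default 25)
#' @param odor_volume_offsets named numeric vector of per-odor multiplicative
#'   offsets on peak flow (and hence volume); default all zero, i.e. no
#'   odor-dependent inhalation volume
#' @param resting_amplitude,resting_freq amplitude (a.u.) and frequency (Hz)
#'   of the sinusoidal resting-breathing baseline
#' @param gamma_shape shape of the gamma flow curve (default 3)
#' @return a list of class `SniffModel`
#' @export
sniffModel <- function(waveform = c("gamma", "triangular"),
                       peak_flow_mean = 1, peak_flow_sd = 0.15,
                       duration_mean = 1.8, duration_sd = 0.25,
                       sampling_rate = 25,
                       odor_volume_offsets = NULL,
                       resting_amplitude = 0.12, resting_freq = 0.25,
                       gamma_shape = 3) {
  waveform <- match.arg(waveform)
  stopifnot(peak_flow_mean > 0, duration_mean > 0, sampling_rate > 0,
            gamma_shape > 1)
  structure(list(waveform = waveform,
                 peak_flow_mean = peak_flow_mean, peak_flow_sd = peak_flow_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 sampling_rate = sampling_rate,
                 odor_volume_offsets = odor_volume_offsets,
                 resting_amplitude = resting_amplitude,
                 resting_freq = resting_freq,
                 gamma_shape = gamma_shape),
            class = "SniffModel")
}

## unit-peak inhalation flow at times tau in [0, duration]
.inhalationShape <- function(tau, duration, waveform, gamma_shape = 3) {
  y <- numeric(length(tau))
  inside <- tau >= 0 & tau <= duration
  if (waveform == "triangular") {
    half <- duration / 2
    y[inside] <- 1 - abs(tau[inside] - half) / half
  } else {
    ## gamma-density-shaped flow rescaled to unit peak; support clipped to
    ## [0, duration] with the mode at duration * (shape-1)/(shape+1)
    k <- gamma_shape
    scale <- duration / (k + 1)            # density support ~ [0, duration]
    mode <- (k - 1) * scale
    peak <- stats::dgamma(mode, shape = k, scale = scale)
    y[inside] <- stats::dgamma(tau[inside], shape = k, scale = scale) / peak
  }
  y
}

#' Generate a respiration trace for one run
#'
#' Returns the sampled airflow series for a single run, with one cued
#' inhalation per trial at stimulus onset superimposed on resting
#' breathing, plus the stored per-trial ground truth.
#'
#' @param events event table rows for one run (see
#'   [generateTrialSequence()])
#' @param model a [sniffModel()]
#' @param seed optional integer seed
#' @param run_duration_s trace length in seconds
#' @return list of class `SniffTrace` with elements `time`, `flow`,
#'   `sampling_rate` and `truth` (data.frame: trial, onset, odor, peak,
#'   duration, volume)
#' @export
generateSniffTrace <- function(events, model = sniffModel(), seed = NULL,
                               run_duration_s = 480) {
  stopifnot(length(unique(events$run)) == 1L)
  .withSeed(seed, {
    fs <- model$sampling_rate
    time <- seq(0, run_duration_s - 1 / fs, by = 1 / fs)
    flow <- model$resting_amplitude *
      sin(2 * pi * model$resting_freq * time + stats::runif(1L, 0, 2 * pi))
    n_tr <- nrow(events)
    peak <- pmax(0.05, stats::rnorm(n_tr, model$peak_flow_mean,
                                    model$peak_flow_sd))
    if (!is.null(model$odor_volume_offsets)) {
      off <- model$odor_volume_offsets[events$odor]
      off[is.na(off)] <- 0
      peak <- peak * (1 + off)
    }
    dur <- pmax(0.3, stats::rnorm(n_tr, model$duration_mean,
                                  model$duration_sd))
    soa <- if (n_tr > 1L) min(diff(sort(events$onset))) else Inf
    if (any(dur >= soa)) {
      stop("overlapping inhalations: sampled duration reaches the ",
           "stimulus-onset asynchrony (", signif(soa, 4), " s)")
    }
    volume <- numeric(n_tr)
    for (i in seq_len(n_tr)) {
      tau <- time - events$onset[i]
      shape <- .inhalationShape(tau, dur[i], model$waveform,
                                model$gamma_shape)
      flow <- flow + peak[i] * shape
      ## truth volume from dense quadrature of the analytic waveform
      tt <- seq(0, dur[i], length.out = 2001L)
      volume[i] <- peak[i] * trapz(tt, .inhalationShape(tt, dur[i],
                                                        model$waveform,
                                                        model$gamma_shape))
    }
    structure(list(time = time, flow = flow, sampling_rate = fs,
                   truth = data.frame(trial = events$trial,
                                      onset = events$onset,
                                      odor = events$odor,
                                      peak = peak, duration = dur,
                                      volume = volume)),
              class = "SniffTrace")
  })
}
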