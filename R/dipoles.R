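#' Subject-level dipole waveform parameters
#'
#' Describes the equivalent-current-dipole (ECD) source waveforms of one
#' subject: for the primary somatosensory cortex (SI) three Gaussian lobes
#' whose latencies correspond to the N20m, P35m and P60m deflections
#' (alternating polarity so that zero crossings separate consecutive lobes),
#' and for the secondary somatosensory cortex (SII) one broad lobe in the
#' 60-200 ms window. Repeated stimulation within a train attenuates each
#' deflection by the recovery factor `1 - exp(-ISI / tau)`, with a distinct
#' recovery time constant per feature, which produces the frequency-dependent
#' habituation seen in somatosensory evoked fields.
#'
#' @param amplitudes Named numeric vector of base lobe amplitudes in nAm for
#'   `N20m`, `P35m`, `P60m` and `SII`.
#' @param taus Named numeric vector of habituation recovery time constants in
#'   seconds for the same four components; larger tau = stronger habituation
#'   at short inter-stimulus intervals.
#' @param jitter_sd Relative standard deviation of log-normal inter-subject
#'   amplitude variation applied when `seed` is given.
#' @param seed Optional integer seed for the inter-subject variation.
#' @return Object of class `dipole_params` with a `lobes` data frame
#'   (columns `feature`, `dipole`, `center_ms`, `sigma_ms`, `sign`,
#'   `amplitude`, `tau`).
#' @export
dipole_subject_params <- function(amplitudes = c(N20m = 10, P35m = 20,
                                                 P60m = 15, SII = 8),
                                  taus = c(N20m = 0.1, P35m = 0.5,
                                           P60m = 1.0, SII = 2.0),
                                  jitter_sd = 0.2, seed = NULL) {
  stopifnot(all(taus > 0))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    amplitudes <- amplitudes * exp(rnorm(length(amplitudes), 0, jitter_sd))
  }
  lobes <- data.frame(
    feature = c("N20m", "P35m", "P60m", "SII"),
    dipole = c("SI", "SI", "SI", "SII"),
    center_ms = c(21, 34, 62, 120),
    sigma_ms = c(1.5, 2.5, 6, 20),
    sign = c(-1, 1, -1, 1),
    amplitude = as.numeric(amplitudes[c("N20m", "P35m", "P60m", "SII")]),
    tau = as.numeric(taus[c("N20m", "P35m", "P60m", "SII")])
  )
  structure(list(lobes = lobes), class = "dipole_params")
}

#' Habituation recovery factor
#'
#' Fractional recovery of a response component after an inter-stimulus
#' interval `isi`, modeled as `1 - exp(-isi / tau)`. The first stimulus of a
#' train is always at full amplitude.
#'
#' @param isi Inter-stimulus-onset interval in seconds.
#' @param tau Recovery time constant in seconds (`tau -> 0` means no
#'   habituation).
#' @return Recovery factor in (0, 1].
#' @export
habituation_factor <- function(isi, tau) {
  stopifnot(all(isi > 0), all(tau >= 0))
  ifelse(tau == 0, 1, 1 - exp(-isi / tau))
}

#' Simulate ECD waveforms for one stimulus train
#'
#' Generates SI and SII dipole time courses (nAm) for one presentation of a
#' stimulus train, sampled at `fs` Hz on an epoch from 200 ms before the
#' first stimulus to `post_ms` after the last stimulus. Each stimulus adds
#' the subject's lobes at its onset, scaled for stimuli after the first by
#' the habituation recovery factor; white Gaussian noise of standard
#' deviation `noise_sd` nAm is added to every sample.
#'
#' @param params A [dipole_subject_params()] object.
#' @param train A [make_stimulus_train()] object.
#' @param noise_sd Additive white noise SD in nAm (0 for a noiseless epoch).
#' @param fs Sampling frequency in Hz (>= 600; default 1000).
#' @param post_ms Epoch extent after the last stimulus in ms; must be at
#'   least 250 so that the SII window of the last stimulus is covered.
#' @param seed Optional integer seed for the noise.
#' @return A `dipole_record`: list with `time` (s, 0 = first stimulus onset),
#'   `waveforms` (matrix, columns `SI` and `SII`), `fs`, `frequency`,
#'   `train` and `params`.
#' @export
simulate_dipole_waveforms <- function(params, train, noise_sd = 1,
                                      fs = 1000, post_ms = 250, seed = NULL) {
  stopifnot(inherits(params, "dipole_params"), inherits(train, "stimulus_train"))
  if (fs < 600) stop("`fs` must be at least 600 Hz")
  if (post_ms < 250) {
    stop("epoch must extend at least 250 ms past the last stimulus")
  }
  t <- seq(-0.2, max(train$onsets) + post_ms / 1000, by = 1 / fs)
  w <- matrix(0, nrow = length(t), ncol = 2,
              dimnames = list(NULL, c("SI", "SII")))
  lob <- params$lobes
  for (k in seq_along(train$onsets)) {
    onset <- train$onsets[k]
    gain <- if (k == 1) rep(1, nrow(lob)) else
      habituation_factor(train$isi, lob$tau)
    for (j in seq_len(nrow(lob))) {
      mu <- onset + lob$center_ms[j] / 1000
      sd_s <- lob$sigma_ms[j] / 1000
      col <- if (lob$dipole[j] == "SI") 1L else 2L
      w[, col] <- w[, col] +
        gain[j] * lob$sign[j] * lob$amplitude[j] * exp(-(t - mu)^2 / (2 * sd_s^2))
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    w <- w + matrix(rnorm(length(w), 0, noise_sd), nrow = nrow(w))
  }
  structure(
    list(time = t, waveforms = w, fs = fs, frequency = train$frequency,
         train = train, params = params),
    class = "dipole_record"
  )
}

#' Simulate a stream of dipole epochs for a run
#'
#' One noisy epoch per stimulus block of a run schedule; epochs are grouped
#' by stimulation frequency for later averaging.
#'
#' @inheritParams simulate_dipole_waveforms
#' @param schedule A [make_run_schedule()] object.
#' @return List of `dipole_record` epochs in block order.
#' @export
simulate_dipole_epochs <- function(params, schedule, noise_sd = 1,
                                   fs = 1000, seed = 1) {
  trains <- attr(schedule, "trains")
  lapply(seq_len(nrow(schedule)), function(k) {
    simulate_dipole_waveforms(params, trains[[as.character(schedule$frequency[k])]],
                              noise_sd = noise_sd, fs = fs,
                              seed = child_seed(seed, k))
  })
}

#' Closed-form lobe area for the simulated waveforms
#'
#' Signed integral of one generated Gaussian lobe over a time window,
#' relative to the stimulus onset: `sign * A * sigma * sqrt(2*pi) *
#' (Phi((b-c)/sigma) - Phi((a-c)/sigma))`, in nAm*s. Used as an independent
#' oracle for feature extraction on noiseless simulated data.
#'
#' @param params A [dipole_subject_params()] object.
#' @param feature One of `"N20m"`, `"P35m"`, `"P60m"`, `"SII"`.
#' @param window_ms Length-2 window in ms post-stimulus (default covers the
#'   whole lobe).
#' @param gain Habituation gain applied to the lobe (default 1).
#' @return Signed area in nAm*s.
#' @export
lobe_auc_closed_form <- function(params, feature,
                                 window_ms = c(-Inf, Inf), gain = 1) {
  lob <- params$lobes[params$lobes$feature == feature, ]
  stopifnot(nrow(lob) == 1)
  c_s <- lob$center_ms / 1000
  s_s <- lob$sigma_ms / 1000
  frac <- pnorm((window_ms[2] / 1000 - c_s) / s_s) -
    pnorm((window_ms[1] / 1000 - c_s) / s_s)
  gain * lob$sign * lob$amplitude * s_s * sqrt(2 * pi) * frac
}
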