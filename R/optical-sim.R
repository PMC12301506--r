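#' Select a ball-shaped gray-matter region
#'
#' Picks the gray-matter voxels within `radius_mm` of a point centered
#' laterally at `center_mm` (x, y) and at the middle of the gray-matter
#' layer in depth. Used to define SI-like and SII-like active regions.
#'
#' @param head A [build_head_phantom()] object.
#' @param center_mm Length-2 lateral center (mm).
#' @param radius_mm Ball radius (mm).
#' @return Integer vector of voxel linear indices (all within gray matter).
#' @export
gm_ball_region <- function(head, center_mm, radius_mm = 5) {
  gm_idx <- which(head$gm_mask)
  zc <- mean(head$coords[gm_idx, 3])
  d <- sqrt((head$coords[gm_idx, 1] - center_mm[1])^2 +
              (head$coords[gm_idx, 2] - center_mm[2])^2 +
              (head$coords[gm_idx, 3] - zc)^2)
  out <- gm_idx[d <= radius_mm]
  if (!length(out)) stop("no gray-matter voxel within `radius_mm`")
  out
}

#' Neurovascular coupling ground truth
#'
#' Defines where and how strongly the MEG feature regressors drive the
#' total-hemoglobin response in the synthetic recordings. Each region is a
#' set of gray-matter voxels with a named coupling weight vector `beta`
#' (micromolar of peak HbT change per unit of the predicted regressor,
#' which has unit peak for a unit impulse). The HbT change is split into
#' oxy/deoxy components as `dHbO2 = hbo2_fraction * dHbT` and
#' `dHbR = (1 - hbo2_fraction) * dHbT`, so their sum is dHbT identically;
#' the default 1.25 gives the typical activation polarity (HbO2 up, HbR
#' down).
#'
#' @param head A [build_head_phantom()] object.
#' @param regions Named list; each element a list with `voxels` (indices
#'   inside gray matter) and `beta` (named numeric, names from
#'   [feature_order()]). An empty list gives a null (no coupling) truth.
#' @param hbo2_fraction Fraction of dHbT assigned to dHbO2.
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(head, regions = list(), hbo2_fraction = 1.25) {
  for (r in regions) {
    stopifnot(!is.null(r$voxels), !is.null(r$beta))
    if (!all(head$gm_mask[r$voxels])) {
      stop("ground-truth regions must lie inside gray matter")
    }
    if (!all(is.finite(r$beta))) stop("coupling weights must be finite")
  }
  structure(list(regions = regions, hbo2_fraction = hbo2_fraction),
            class = "ground_truth")
}

#' Physiological and instrument noise configuration
#'
#' Noise model for the log-amplitude of each optical channel: white Gaussian
#' sample noise, a random linear drift over the run, and sinusoidal
#' physiological oscillations (defaults: ~1 Hz cardiac, 0.3 Hz respiratory
#' and 0.1 Hz Mayer waves) with independent random phase per channel.
#' Amplitudes are in log-amplitude units (0.01 is roughly a 1% amplitude
#' modulation).
#'
#' @param white_sd White noise standard deviation per sample.
#' @param drift_amplitude Maximum absolute linear drift over the whole run.
#' @param sinusoids Data frame with `freq` (Hz) and `amplitude` columns.
#' @return A `noise_config` list.
#' @export
optical_noise_config <- function(white_sd = 0.005, drift_amplitude = 0.02,
                                 sinusoids = data.frame(
                                   freq = c(1.0, 0.3, 0.1),
                                   amplitude = c(0.005, 0.008, 0.005))) {
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 sinusoids = sinusoids),
            class = "noise_config")
}

#' Simulate a two-wavelength optical recording for one run
#'
#' Forward model: within each active region the voxel HbT change is the sum
#' over MEG features of the coupling weight times the feature's predicted
#' hemodynamic regressor (per-stimulus feature values placed at the stimulus
#' onsets of every block and convolved with the canonical HRF at the native
#' sampling rate). HbT is split into HbO2/HbR, converted to absorption
#' changes at both wavelengths through the extinction coefficients,
#' projected to channel log-amplitude changes through the sensitivity
#' matrices, and combined with channel noise:
#' `A(t) = A0 * exp(dlogA(t) + noise(t))`.
#'
#' @param schedule A [make_run_schedule()] object.
#' @param truth A [make_ground_truth()] object.
#' @param features Per-stimulus feature values of this subject: data frame
#'   with `frequency`, `stimulus_index`, `feature_id`, `value` (see
#'   [extract_features()]). Only the features named in the truth's coupling
#'   weights are used; may be `NULL` for a null truth.
#' @param sensitivity A [simulate_sensitivity()] object.
#' @param noise_cfg An [optical_noise_config()].
#' @param seed Integer seed; the recording is reproducible from it.
#' @param fs Native sampling frequency in Hz (default 10).
#' @param hrf Canonical HRF used in the forward coupling; evaluated on the
#'   native grid.
#' @param extinction Extinction matrix, rows matching the sensitivity
#'   wavelengths.
#' @return An `optical_recording`: list with `time`, `fs`, `A` (list per
#'   wavelength of time x pairs amplitude matrices), `pairs`, `dlogA_signal`
#'   (the noiseless evoked log-amplitude change) and `hbt_regressor`
#'   (voxel-level HbT time courses per region).
#' @export
simulate_optical_run <- function(schedule, truth, features, sensitivity,
                                 noise_cfg = optical_noise_config(),
                                 seed = 1, fs = 10, hrf = NULL,
                                 extinction = hb_extinction_coefficients()) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  duration <- attr(schedule, "duration")
  # run length rounded up to an FFT-friendly sample count (trailing rest)
  nt <- stats::nextn(floor(duration * fs) + 1, c(2, 3, 5))
  t <- (seq_len(nt) - 1) / fs
  if (is.null(hrf)) hrf <- canonical_hrf(dt = 1 / fs)
  if (abs(hrf$dt - 1 / fs) > 1e-12) stop("HRF grid must match `fs`")
  trains <- attr(schedule, "trains")
  pairs <- sensitivity$layout$pairs
  np <- nrow(pairs)
  wls <- as.character(sensitivity$wavelengths)

  # evoked voxel HbT per region
  dlogA <- lapply(wls, function(w) matrix(0, nt, np))
  names(dlogA) <- wls
  hbt_regressor <- list()
  if (length(truth$regions)) {
    used_feats <- unique(unlist(lapply(truth$regions,
                                       function(r) names(r$beta))))
    m_feat <- matrix(0, nt, length(used_feats),
                     dimnames = list(NULL, used_feats))
    for (fid in used_feats) {
      imp <- numeric(nt)
      for (b in seq_len(nrow(schedule))) {
        train <- trains[[as.character(schedule$frequency[b])]]
        vals <- feature_values_for(features, schedule$frequency[b], fid,
                                   train$n_stimuli)
        bins <- round((schedule$start_time[b] + train$onsets) * fs) + 1
        if (any(bins > nt)) stop("feature regressors do not cover the run")
        imp[bins] <- imp[bins] + vals
      }
      m_feat[, fid] <- linear_convolve(imp, hrf$h)[seq_len(nt)]
    }
    f <- truth$hbo2_fraction
    for (rn in names(truth$regions)) {
      reg <- truth$regions[[rn]]
      hbt <- as.numeric(m_feat[, names(reg$beta), drop = FALSE] %*% reg$beta)
      hbt_regressor[[rn]] <- hbt
      for (w in wls) {
        # dmua per region voxel = (E_HbO2 * f + E_HbR * (1 - f)) * dHbT
        coef <- extinction[w, "HbO2"] * f + extinction[w, "HbR"] * (1 - f)
        gain <- rowSums(sensitivity$J[[w]][, reg$voxels, drop = FALSE]) * coef
        dlogA[[w]] <- dlogA[[w]] + outer(hbt, gain)
      }
    }
  }

  # baseline amplitude per pair: diffuse attenuation with separation
  A0 <- exp(-sensitivity$mu_eff * pairs$separation) / pairs$separation^2
  A0 <- A0 / max(A0)

  A <- list()
  for (w in wls) {
    noise <- matrix(rnorm(nt * np, 0, noise_cfg$white_sd), nt, np)
    slope <- runif(np, -1, 1) * noise_cfg$drift_amplitude
    noise <- noise + outer(t / max(t), slope)
    for (s in seq_len(nrow(noise_cfg$sinusoids))) {
      f0 <- noise_cfg$sinusoids$freq[s]
      amp <- noise_cfg$sinusoids$amplitude[s]
      ph <- runif(np, 0, 2 * pi)
      # sin(w t + phi_j) expanded so the time vectors are computed once
      noise <- noise + amp * (outer(sin(2 * pi * f0 * t), cos(ph)) +
                                outer(cos(2 * pi * f0 * t), sin(ph)))
    }
    A[[w]] <- sweep(exp(dlogA[[w]] + noise), 2, A0, `*`)
  }

  structure(
    list(time = t, fs = fs, A = A, pairs = pairs, schedule = schedule,
         dlogA_signal = dlogA, hbt_regressor = hbt_regressor,
         truth = truth),
    class = "optical_recording"
  )
}

# per-stimulus feature values for one block, zero-filled when absent
feature_values_for <- function(features, frequency, feature_id, n_stimuli) {
  if (is.null(features)) return(numeric(n_stimuli))
  sel <- features$frequency == frequency & features$feature_id == feature_id
  ff <- features[sel, ]
  if (!nrow(ff)) return(numeric(n_stimuli))
  vals <- numeric(n_stimuli)
  vals[ff$stimulus_index] <- ff$value
  vals
}
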