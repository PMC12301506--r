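#' Canonical hemodynamic response function
#'
#' Difference-of-gamma-density kernel with the usual defaults (response delay
#' 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6,
#' truncated at 32 s), constructed on a 20 Hz grid. To account for the
#' slightly faster time course of total-hemoglobin responses compared to
#' BOLD, the kernel's time-to-peak is shortened by `peak_shift` seconds
#' (default 0.5 s). By default this is implemented by reducing the response
#' delay parameter (6 -> 5.5 s), which preserves `h(0) = 0`; `shift_mode =
#' "shift"` instead translates the default kernel in time.
#'
#' @param dt Sampling interval in seconds (default 0.05, i.e. 20 Hz).
#' @param response_delay,undershoot_delay Gamma delays in seconds.
#' @param response_dispersion,undershoot_dispersion Gamma dispersions (s).
#' @param undershoot_ratio Relative amplitude of the undershoot gamma.
#' @param duration Kernel length in seconds.
#' @param peak_shift Reduction of the time-to-peak in seconds (0 disables).
#' @param shift_mode `"delay"` (default) or `"shift"`, see above.
#' @param normalize If `TRUE` (default) scale the kernel to unit peak.
#' @return A `canonical_hrf`: list with `t`, `h`, `dt` and the parameters.
#' @export
canonical_hrf <- function(dt = 0.05, response_delay = 6, undershoot_delay = 16,
                          response_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6, duration = 32,
                          peak_shift = 0.5, shift_mode = c("delay", "shift"),
                          normalize = TRUE) {
  if (dt <= 0) stop("`dt` must be positive")
  shift_mode <- match.arg(shift_mode)
  t <- seq(0, duration, by = dt)
  eval_kernel <- function(delay1) {
    stats::dgamma(t, shape = delay1 / response_dispersion,
                  rate = 1 / response_dispersion) -
      undershoot_ratio *
        stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                      rate = 1 / undershoot_dispersion)
  }
  if (shift_mode == "delay") {
    h <- eval_kernel(response_delay - peak_shift)
  } else {
    h0 <- eval_kernel(response_delay)
    shift_n <- round(peak_shift / dt)
    h <- c(h0[-seq_len(shift_n)], rep(0, shift_n))
  }
  if (normalize) h <- h / max(h)
  structure(
    list(t = t, h = h, dt = dt,
         params = list(response_delay = response_delay,
                       undershoot_delay = undershoot_delay,
                       response_dispersion = response_dispersion,
                       undershoot_dispersion = undershoot_dispersion,
                       undershoot_ratio = undershoot_ratio,
                       duration = duration, peak_shift = peak_shift,
                       shift_mode = shift_mode)),
    class = "canonical_hrf"
  )
}

#' Impulse series of per-stimulus feature values
#'
#' Places one nonzero sample per stimulus on a regular grid: each stimulus
#' onset is rounded to the nearest grid bin and assigned that stimulus's
#' feature value (the per-peak AUC for the AUC features, the RMS value for
#' the RMS features).
#'
#' @param values Numeric feature values, one per stimulus (train order).
#' @param train A [make_stimulus_train()] object supplying the onsets.
#' @param dt Grid interval in seconds (default 0.05, 20 Hz).
#' @param duration Grid length in seconds; must cover the last onset.
#'   Default: train end + 32 s (the HRF support).
#' @return List with `t` and `n` (the impulse series).
#' @export
build_impulse_series <- function(values, train, dt = 0.05,
                                 duration = max(train$onsets) + 32) {
  stopifnot(length(values) == train$n_stimuli)
  t <- seq(0, duration, by = dt)
  if (max(train$onsets) > max(t)) stop("stimulus onsets outside the grid")
  n <- numeric(length(t))
  bins <- round(train$onsets / dt) + 1
  n[bins] <- n[bins] + values
  list(t = t, n = n, dt = dt)
}

#' Predicted hemodynamic response for one feature and train
#'
#' Linear convolution of an impulse series of feature values with the
#' canonical HRF, constructed at 20 Hz and then resampled to 2 Hz by
#' anti-aliased decimation. The summary measures used by the correlation
#' analyses are the trapezoidal AUC over 1-9 s after train onset and the
#' regressor values sampled at 1, 3, 5, 7 and 9 s (0.5 Hz spacing avoids
#' strong temporal correlation between adjacent samples).
#'
#' @param n Impulse series from [build_impulse_series()].
#' @param hrf A [canonical_hrf()] object on the same grid (`dt` must match).
#' @param auc_window AUC integration window in seconds (default 1-9 s).
#' @param sample_times Sampling times in seconds (default 1, 3, 5, 7, 9).
#' @return A `predicted_response`: list with the 20 Hz regressor (`t20`,
#'   `m20`), the 2 Hz regressor (`t2`, `m2`), `auc` and `samples`.
#' @export
predict_response <- function(n, hrf, auc_window = c(1, 9),
                             sample_times = c(1, 3, 5, 7, 9)) {
  if (abs(n$dt - hrf$dt) > 1e-12) stop("grid mismatch between `n` and `hrf`")
  m20 <- linear_convolve(n$n, hrf$h)
  t20 <- (seq_along(m20) - 1) * n$dt
  fs20 <- 1 / n$dt
  factor <- as.integer(round(fs20 / 2))
  m2 <- decimate_signal(m20, factor, fs20)
  t2 <- t20[seq(1, length(t20), by = factor)]
  sel <- t2 >= auc_window[1] & t2 <= auc_window[2]
  auc <- trapz(t2[sel], m2[sel])
  samples <- m2[match(sample_times, round(t2, 9))]
  if (anyNA(samples)) stop("`sample_times` not on the 2 Hz grid")
  structure(
    list(t20 = t20, m20 = m20, t2 = t2, m2 = m2, auc = auc,
         samples = samples, sample_times = sample_times),
    class = "predicted_response"
  )
}

#' Discrete linear convolution
#'
#' Full ("open") linear convolution of two series; length
#' `length(x) + length(h) - 1`.
#' @keywords internal
linear_convolve <- function(x, h) {
  as.numeric(stats::convolve(x, rev(h), type = "open"))
}

#' Predicted responses for all features of a subject
#'
#' Builds, for every stimulation frequency and feature, the impulse series
#' from the extracted per-stimulus feature values and convolves it with the
#' canonical HRF.
#'
#' @param features Feature data frame from [extract_subject_features()] (or
#'   [extract_features()] with a `subject` column).
#' @param trains Named list of `stimulus_train` objects keyed by frequency.
#' @param hrf A [canonical_hrf()]; default kernel.
#' @return Data frame with columns `subject`, `frequency`, `feature_id`,
#'   `auc_pred` and a `samples` matrix column (5 columns).
#' @export
predict_subject_responses <- function(features, trains, hrf = canonical_hrf()) {
  keys <- unique(features[, c("subject", "frequency", "feature_id")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- features$subject == keys$subject[i] &
      features$frequency == keys$frequency[i] &
      features$feature_id == keys$feature_id[i]
    ff <- features[sel, ]
    ff <- ff[order(ff$stimulus_index), ]
    train <- trains[[as.character(keys$frequency[i])]]
    imp <- build_impulse_series(ff$value, train, dt = hrf$dt)
    pr <- predict_response(imp, hrf)
    cbind(keys[i, , drop = FALSE], auc_pred = pr$auc,
          samples = matrix(pr$samples, nrow = 1))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble the group design (y registry and predictor matrix X)
#'
#' Orders the subject-by-frequency cells (subjects outer, the four
#' frequencies inner) and builds the matrix `X` whose six columns are the
#' predicted response AUCs of the MEG features in protocol order. Cells with
#' missing measurements or an incomplete feature set are dropped from both
#' the registry and `X` with a message.
#'
#' @param measured_auc Data frame with columns `subject`, `frequency`, `auc`
#'   (the measured hemodynamic AUC; may be `NA` for missing cells).
#' @param predictions Data frame from [predict_subject_responses()].
#' @return List with `y` (numeric vector), `X` (matrix, 6 columns in
#'   [feature_order()]), and `rows` (registry data frame `subject`,
#'   `frequency`).
#' @export
assemble_design <- function(measured_auc, predictions) {
  measured_auc <- measured_auc[order(measured_auc$subject,
                                     measured_auc$frequency), ]
  feats <- feature_order()
  keep <- logical(nrow(measured_auc))
  X <- matrix(NA_real_, nrow(measured_auc), length(feats),
              dimnames = list(NULL, feats))
  for (i in seq_len(nrow(measured_auc))) {
    sel <- predictions$subject == measured_auc$subject[i] &
      predictions$frequency == measured_auc$frequency[i]
    pp <- predictions[sel, ]
    if (all(feats %in% pp$feature_id) && !is.na(measured_auc$auc[i])) {
      X[i, ] <- pp$auc_pred[match(feats, pp$feature_id)]
      keep[i] <- TRUE
    }
  }
  if (any(!keep)) {
    message("dropping ", sum(!keep), " incomplete subject x frequency cell(s)")
  }
  list(y = measured_auc$auc[keep], X = X[keep, , drop = FALSE],
       rows = measured_auc[keep, c("subject", "frequency")])
}
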