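#' MEG feature window statistics
#'
#' Mean and standard deviation (ms, post-stimulus) of the beginning and end
#' points of the dipole-waveform feature windows: the SI N20m, P35m and P60m
#' deflections, the fixed SII 60-200 ms window, and the fixed 10-200 ms RMS
#' windows for the SI and SII dipoles.
#'
#' @return Data frame with columns `feature_id`, `dipole`, `kind`
#'   (`"auc"` or `"rms"`), `begin_mean`, `begin_sd`, `end_mean`, `end_sd`.
#' @export
feature_windows <- function() {
  data.frame(
    feature_id = c("N20m", "P35m", "P60m", "SII60_200", "SI_RMS", "SII_RMS"),
    dipole = c("SI", "SI", "SI", "SII", "SI", "SII"),
    kind = c("auc", "auc", "auc", "auc", "rms", "rms"),
    begin_mean = c(18, 28, 42, 60, 10, 10),
    begin_sd = c(2, 2, 8, 0, 0, 0),
    end_mean = c(27, 40, 135, 200, 200, 200),
    end_sd = c(2, 7, 26, 0, 0, 0)
  )
}

#' Protocol order of the MEG features
#' @return Character vector of the six feature identifiers.
#' @export
feature_order <- function() {
  c("N20m", "P35m", "P60m", "SII60_200", "SI_RMS", "SII_RMS")
}

#' Preprocess and average dipole epochs per stimulation frequency
#'
#' Applies, per epoch: optional blanking of the stimulator artifact over
#' 0-10 ms after each stimulus onset (samples replaced by a running-median
#' filtered version of the waveform), a 50 Hz zero-phase notch filter, and a
#' 250 Hz zero-phase low-pass, then averages the accepted epochs of each
#' stimulation frequency.
#'
#' @param epochs List of `dipole_record` epochs (see
#'   [simulate_dipole_waveforms()]); epochs are grouped by their `frequency`.
#' @param blank_ms Length-2 window (ms post-stimulus) to blank with the
#'   median filter, or `NULL` to skip blanking.
#' @param median_k Odd running-median width in samples used for blanking.
#' @param notch_hz Power-line notch frequency (Hz); `NULL` to skip.
#' @param lowpass_hz Low-pass cutoff (Hz); `NULL` to skip.
#' @param expected_frequencies Optional frequencies that must be present;
#'   missing conditions are reported with a warning and returned as `NULL`.
#' @return Named list (by frequency) of averaged `dipole_record` objects;
#'   each carries an `n_epochs` attribute.
#' @export
preprocess_and_average <- function(epochs, blank_ms = c(0, 10),
                                   median_k = 31, notch_hz = 50,
                                   lowpass_hz = 250,
                                   expected_frequencies = NULL) {
  stopifnot(length(epochs) >= 1)
  freqs <- vapply(epochs, `[[`, numeric(1), "frequency")
  processed <- lapply(epochs, function(ep) {
    w <- ep$waveforms
    for (j in seq_len(ncol(w))) {
      x <- w[, j]
      if (!is.null(blank_ms)) {
        med <- stats::runmed(x, k = min(median_k, 2 * (length(x) %/% 2) - 1),
                             endrule = "median")
        for (onset in ep$train$onsets) {
          sel <- ep$time >= onset + blank_ms[1] / 1000 &
            ep$time <= onset + blank_ms[2] / 1000
          x[sel] <- med[sel]
        }
      }
      if (!is.null(notch_hz)) x <- notch_zero_phase(x, notch_hz, ep$fs)
      if (!is.null(lowpass_hz)) x <- lowpass_zero_phase(x, lowpass_hz, ep$fs)
      w[, j] <- x
    }
    ep$waveforms <- w
    ep
  })
  out <- lapply(unique(freqs), function(f) {
    grp <- processed[freqs == f]
    w <- Reduce(`+`, lapply(grp, `[[`, "waveforms")) / length(grp)
    avg <- grp[[1]]
    avg$waveforms <- w
    attr(avg, "n_epochs") <- length(grp)
    avg
  })
  names(out) <- as.character(unique(freqs))
  if (!is.null(expected_frequencies)) {
    missing <- setdiff(as.character(expected_frequencies), names(out))
    if (length(missing)) {
      warning("missing condition(s): ", paste(missing, collapse = ", "))
      for (m in missing) out[m] <- list(NULL)
    }
  }
  out
}

#' Remove inter-stimulus baseline drift from an averaged epoch
#'
#' At high stimulation frequencies the averaged dipole signal does not return
#' to baseline between stimuli. The baseline is estimated by taking the mean
#' over a -10 to 0 ms window before each stimulus onset, linearly
#' interpolating these values across the epoch (constant extrapolation at the
#' ends), low-pass filtering the constructed piecewise-linear function at
#' 8 Hz (-3 dB, zero phase), and subtracting it from the averaged waveform.
#'
#' @param avg An averaged `dipole_record`.
#' @param pre_ms Length-2 pre-stimulus window in ms (default -10 to 0).
#' @param smooth_hz Low-pass cutoff for the baseline function in Hz.
#' @return The corrected `dipole_record`; the fitted baseline is attached as
#'   attribute `baseline`.
#' @export
remove_baseline_drift <- function(avg, pre_ms = c(-10, 0), smooth_hz = 8) {
  onsets <- avg$train$onsets
  w <- avg$waveforms
  base <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  for (j in seq_len(ncol(w))) {
    knots_t <- onsets + mean(pre_ms) / 1000
    knots_v <- vapply(onsets, function(o) {
      sel <- avg$time >= o + pre_ms[1] / 1000 & avg$time < o + pre_ms[2] / 1000
      mean(w[sel, j])
    }, numeric(1))
    b <- stats::approx(knots_t, knots_v, xout = avg$time, rule = 2)$y
    if (length(onsets) == 1) b <- rep(knots_v, length(avg$time))
    b <- lowpass_zero_phase(b, smooth_hz, avg$fs)
    base[, j] <- b
  }
  avg$waveforms <- w - base
  attr(avg, "baseline") <- base
  avg
}

#' Extract per-stimulus MEG features from an averaged epoch
#'
#' For every stimulus in the train: the SI N20m, P35m and P60m peaks are
#' located by signed extremum search within their expected windows (mean
#' +/- 3 SD of the window statistics, constrained to lie after the previous
#' peak), the window of each peak is bounded by the zero crossings between
#' consecutive peaks (falling back to the minimum of the absolute signal
#' when no crossing exists), and the signed trapezoidal area under the curve
#' (AUC, nAm s) is integrated over that window. The SII AUC uses the fixed
#' 60-200 ms window, and the SI and SII RMS features use the fixed 10-200 ms
#' window (nAm).
#'
#' @param avg An averaged, baseline-corrected `dipole_record` with `SI` and
#'   `SII` waveform columns.
#' @param rectify If `TRUE`, report absolute values of the AUC features;
#'   default `FALSE` keeps the signed convention of the dipole fit.
#' @param windows Feature window statistics; defaults to [feature_windows()].
#' @return Data frame with columns `frequency`, `stimulus_index`,
#'   `feature_id`, `value`, `window_begin_ms`, `window_end_ms`.
#' @export
extract_features <- function(avg, rectify = FALSE, windows = feature_windows()) {
  onsets <- avg$train$onsets
  isi_ms <- if (length(onsets) > 1) 1000 / avg$frequency else Inf
  si_peaks <- windows[windows$kind == "auc" & windows$dipole == "SI", ]
  # alternating lobe polarity (N20m opposite to P35m, P60m opposite again);
  # the overall sign convention of the dipole fit is estimated from the
  # dominant P35m lobe of the first stimulus, so extraction is equivariant
  # under an overall sign flip of the waveform
  rel1 <- (avg$time - onsets[1]) * 1000
  sel1 <- which(rel1 >= 28 & rel1 <= 40)
  si1 <- avg$waveforms[sel1, "SI"]
  pol <- sign(si1[which.max(abs(si1))])
  if (length(pol) == 0 || pol == 0) pol <- 1
  peak_sign <- pol * c(N20m = -1, P35m = 1, P60m = -1)
  rows <- list()

  for (k in seq_along(onsets)) {
    o <- onsets[k]
    rel_ms <- (avg$time - o) * 1000
    limit_ms <- min(isi_ms + 10, max(rel_ms))
    si <- avg$waveforms[, "SI"]
    sii <- avg$waveforms[, "SII"]

    # --- SI peaks -------------------------------------------------------
    peak_ms <- numeric(0)
    for (p in seq_len(nrow(si_peaks))) {
      lo <- max(si_peaks$begin_mean[p] - 3 * si_peaks$begin_sd[p],
                if (p > 1) peak_ms[p - 1] + 1 else 10)
      hi <- min(si_peaks$end_mean[p] + 3 * si_peaks$end_sd[p], limit_ms)
      sel <- which(rel_ms >= lo & rel_ms <= hi)
      if (!length(sel)) stop("empty peak search window for ",
                             si_peaks$feature_id[p])
      s <- peak_sign[[si_peaks$feature_id[p]]]
      peak_idx <- sel[which.max(s * si[sel])]
      peak_ms[p] <- rel_ms[peak_idx]
    }
    # window bounds between consecutive peaks: zero crossing, else min |x|
    bound_between <- function(a_ms, b_ms) {
      sel <- which(rel_ms > a_ms & rel_ms < b_ms)
      if (length(sel) < 2) return((a_ms + b_ms) / 2)
      x <- si[sel]
      cross <- which(x[-1] * x[-length(x)] <= 0 & (x[-1] != 0 | x[-length(x)] != 0))
      if (length(cross)) return(rel_ms[sel[cross[1]]])
      rel_ms[sel[which.min(abs(x))]]
    }
    edges <- numeric(nrow(si_peaks) + 1)
    edges[1] <- bound_between(10, peak_ms[1])
    for (p in seq_len(nrow(si_peaks) - 1)) {
      edges[p + 1] <- bound_between(peak_ms[p], peak_ms[p + 1])
    }
    edges[nrow(si_peaks) + 1] <- bound_between(peak_ms[nrow(si_peaks)],
                                               min(limit_ms, 213))
    for (p in seq_len(nrow(si_peaks))) {
      sel <- which(rel_ms >= edges[p] & rel_ms <= edges[p + 1])
      auc <- trapz(rel_ms[sel] / 1000, si[sel])
      rows[[length(rows) + 1]] <- data.frame(
        frequency = avg$frequency, stimulus_index = k,
        feature_id = si_peaks$feature_id[p],
        value = if (rectify) abs(auc) else auc,
        window_begin_ms = edges[p], window_end_ms = edges[p + 1]
      )
    }

    # --- SII AUC and RMS features --------------------------------------
    sel <- which(rel_ms >= 60 & rel_ms <= 200)
    auc <- trapz(rel_ms[sel] / 1000, sii[sel])
    rows[[length(rows) + 1]] <- data.frame(
      frequency = avg$frequency, stimulus_index = k, feature_id = "SII60_200",
      value = if (rectify) abs(auc) else auc,
      window_begin_ms = 60, window_end_ms = 200
    )
    sel <- which(rel_ms >= 10 & rel_ms <= 200)
    for (fid in c("SI_RMS", "SII_RMS")) {
      d <- if (fid == "SI_RMS") "SI" else "SII"
      rows[[length(rows) + 1]] <- data.frame(
        frequency = avg$frequency, stimulus_index = k, feature_id = fid,
        value = sqrt(mean(avg$waveforms[sel, d]^2)),
        window_begin_ms = 10, window_end_ms = 200
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for all frequencies of a subject
#'
#' Convenience wrapper: baseline-corrects each frequency-specific average and
#' extracts the per-stimulus features.
#'
#' @param averages Named list from [preprocess_and_average()].
#' @param subject Subject identifier added as a column.
#' @param ... Passed to [extract_features()].
#' @return Combined feature data frame.
#' @export
extract_subject_features <- function(averages, subject = 1, ...) {
  res <- lapply(averages[!vapply(averages, is.null, logical(1))], function(avg) {
    extract_features(remove_baseline_drift(avg), ...)
  })
  out <- do.call(rbind, res)
  out <- cbind(subject = subject, out)
  rownames(out) <- NULL
  out
}
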