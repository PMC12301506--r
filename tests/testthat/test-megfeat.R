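make_epoch <- function(train, fill = 0, fs = 1000) {
  p <- dipole_subject_params()
  rec <- simulate_dipole_waveforms(p, train, noise_sd = 0, fs = fs)
  rec$waveforms[] <- fill
  rec
}

test_that("averaging identical epochs returns the epoch and noise shrinks as 1/sqrt(N)", {
  p <- dipole_subject_params()
  tr <- make_stimulus_train(1)
  ep <- simulate_dipole_waveforms(p, tr, noise_sd = 0)
  avg <- preprocess_and_average(list(ep, ep, ep), blank_ms = NULL,
                                notch_hz = NULL, lowpass_hz = NULL)
  expect_equal(avg[["1"]]$waveforms, ep$waveforms)
  # white-noise epochs: residual SD after averaging N epochs ~ sd/sqrt(N)
  sds <- vapply(c(4, 16), function(N) {
    eps <- lapply(seq_len(N), function(k) {
      simulate_dipole_waveforms(p, tr, noise_sd = 5, seed = k + 100)
    })
    avg <- preprocess_and_average(eps, blank_ms = NULL, notch_hz = NULL,
                                  lowpass_hz = NULL)
    sd(avg[["1"]]$waveforms[, "SI"] - ep$waveforms[, "SI"])
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.25)
})

test_that("median blanking removes a stimulator spike shortly after onset", {
  p <- dipole_subject_params()
  tr <- make_stimulus_train(0.5)
  ep <- simulate_dipole_waveforms(p, tr, noise_sd = 0)
  spike_at <- which.min(abs(ep$time - 0.005))  # 5 ms post-stimulus
  ep$waveforms[spike_at, "SI"] <- 500
  avg <- preprocess_and_average(list(ep), notch_hz = NULL, lowpass_hz = NULL)
  expect_lt(abs(avg[["0.5"]]$waveforms[spike_at, "SI"]), 5)
})

test_that("missing conditions are flagged", {
  p <- dipole_subject_params()
  ep <- simulate_dipole_waveforms(p, make_stimulus_train(1), noise_sd = 0)
  expect_warning(avg <- preprocess_and_average(list(ep),
                                               expected_frequencies = c(1, 4)),
                 "missing condition")
  expect_null(avg[["4"]])
})

test_that("baseline removal zeroes constant offsets and leaves zero alone", {
  tr <- make_stimulus_train(4)
  ep <- make_epoch(tr, fill = 3.5)
  out <- remove_baseline_drift(ep)
  expect_lt(max(abs(out$waveforms)), 0.05)
  zero <- make_epoch(tr, fill = 0)
  expect_equal(remove_baseline_drift(zero)$waveforms, zero$waveforms)
})

test_that("baseline removal suppresses a slow ramp across a 4 Hz train", {
  tr <- make_stimulus_train(4)
  ep <- make_epoch(tr)
  ramp <- seq(0, 10, length.out = length(ep$time))
  ep$waveforms[, "SI"] <- ramp
  out <- remove_baseline_drift(ep)
  pre_means <- vapply(tr$onsets, function(o) {
    sel <- ep$time >= o - 0.010 & ep$time < o
    mean(out$waveforms[sel, "SI"])
  }, numeric(1))
  expect_true(all(abs(pre_means) < 0.05 * diff(range(ramp))))
})

test_that("baseline removal is close to idempotent", {
  p <- dipole_subject_params()
  tr <- make_stimulus_train(4)
  ep <- simulate_dipole_waveforms(p, tr, noise_sd = 0)
  ep$waveforms[, "SI"] <- ep$waveforms[, "SI"] +
    seq(0, 5, length.out = length(ep$time))
  once <- remove_baseline_drift(ep)
  twice <- remove_baseline_drift(once)
  change1 <- max(abs(once$waveforms - ep$waveforms))
  change2 <- max(abs(twice$waveforms - once$waveforms))
  expect_lt(change2, 0.01 * change1)
})

test_that("AUC and RMS features are linear in the waveform", {
  p <- dipole_subject_params()
  rec <- simulate_dipole_waveforms(p, make_stimulus_train(1), noise_sd = 0)
  f1 <- extract_features(rec)
  rec2 <- rec
  rec2$waveforms <- rec$waveforms * -2.5
  f2 <- extract_features(rec2)
  auc <- f1$feature_id %in% c("N20m", "P35m", "P60m", "SII60_200")
  expect_equal(f2$value[auc], -2.5 * f1$value[auc], tolerance = 1e-6)
  expect_equal(f2$value[!auc], 2.5 * f1$value[!auc], tolerance = 1e-6)
})

test_that("constant segments give rectangle AUC and flat RMS", {
  tr <- make_stimulus_train(0.5)
  ep <- make_epoch(tr, fill = 5)
  rel <- ep$time * 1000
  sel <- rel >= 60 & rel <= 200
  auc <- trapz(rel[sel] / 1000, ep$waveforms[sel, "SII"])
  expect_equal(auc, 5 * 0.140, tolerance = 1e-9)
  sel <- rel >= 10 & rel <= 200
  expect_equal(sqrt(mean(ep$waveforms[sel, "SI"]^2)), 5)
})

test_that("reported SI windows are ordered and non-overlapping", {
  p <- dipole_subject_params()
  for (f in c(0.5, 2, 4)) {
    rec <- simulate_dipole_waveforms(p, make_stimulus_train(f), noise_sd = 0)
    feats <- extract_features(rec)
    for (k in unique(feats$stimulus_index)) {
      w <- feats[feats$stimulus_index == k &
                   feats$feature_id %in% c("N20m", "P35m", "P60m"), ]
      w <- w[match(c("N20m", "P35m", "P60m"), w$feature_id), ]
      expect_true(all(diff(w$window_begin_ms) > 0))
      expect_true(all(w$window_begin_ms < w$window_end_ms))
      expect_true(all(w$window_end_ms[-3] <= w$window_begin_ms[-1] + 1e-9))
    }
  }
})
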