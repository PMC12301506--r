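# forward optical simulation and its consistency with the inverse chain

quiet_noise <- function() {
  optical_noise_config(white_sd = 0, drift_amplitude = 0,
                       sinusoids = data.frame(freq = 1, amplitude = 0))
}

test_that("ground truth regions must lie in gray matter and weights be finite", {
  head <- small_head()
  gm_region <- gm_ball_region(head, c(20, 20), 6)
  expect_true(all(head$gm_mask[gm_region]))
  expect_error(make_ground_truth(head, list(a = list(voxels = 1,
                                                     beta = c(P35m = 1)))),
               "gray matter")
  expect_error(make_ground_truth(head, list(a = list(voxels = gm_region,
                                                     beta = c(P35m = Inf)))),
               "finite")
  # the HbT split sums to HbT by construction
  truth <- make_ground_truth(head, list(), hbo2_fraction = 1.25)
  expect_equal(truth$hbo2_fraction + (1 - truth$hbo2_fraction), 1)
})

test_that("optical recordings are reproducible and positive", {
  head <- small_head(); sens <- small_sensitivity()
  sch <- make_run_schedule(seed = 5, n_repetitions = 1)
  truth <- make_ground_truth(head, list())
  a <- simulate_optical_run(sch, truth, NULL, sens, seed = 9)
  b <- simulate_optical_run(sch, truth, NULL, sens, seed = 9)
  expect_identical(a$A, b$A)
  expect_true(all(a$A[["758"]] > 0))
  d <- simulate_optical_run(sch, truth, NULL, sens, seed = 10)
  expect_false(identical(a$A, d$A))
})

test_that("doubling the coupling doubles the evoked log-amplitude change", {
  head <- small_head(); sens <- small_sensitivity()
  sch <- make_run_schedule(seed = 6, n_repetitions = 1)
  reg <- gm_ball_region(head, c(20, 20), 6)
  feats <- data.frame(frequency = rep(c(0.5, 1, 2, 4), times = c(2, 3, 5, 9)),
                      stimulus_index = c(1:2, 1:3, 1:5, 1:9),
                      feature_id = "P35m", value = 0.1)
  t1 <- make_ground_truth(head, list(a = list(voxels = reg,
                                              beta = c(P35m = 10))))
  t2 <- make_ground_truth(head, list(a = list(voxels = reg,
                                              beta = c(P35m = 20))))
  r1 <- simulate_optical_run(sch, t1, feats, sens, quiet_noise(), seed = 1)
  r2 <- simulate_optical_run(sch, t2, feats, sens, quiet_noise(), seed = 1)
  expect_equal(r2$dlogA_signal[["758"]], 2 * r1$dlogA_signal[["758"]],
               tolerance = 1e-10)
  expect_equal(max(abs(r2$hbt_regressor$a)), 2 * max(abs(r1$hbt_regressor$a)))
})

test_that("a null truth yields recordings with no evoked component", {
  head <- small_head(); sens <- small_sensitivity()
  sch <- make_run_schedule(seed = 6, n_repetitions = 1)
  truth <- make_ground_truth(head, list())
  r <- simulate_optical_run(sch, truth, NULL, sens, quiet_noise(), seed = 1)
  expect_equal(max(abs(r$dlogA_signal[["758"]])), 0)
  # constant amplitudes: preprocessing returns (numerically) zero
  prep <- preprocess_amplitudes(r)
  expect_lt(max(abs(prep$Y[["758"]])), 1e-8)
})

test_that("noiseless data passed through the inverse chain recovers the regional HbT AUC", {
  # forward/inverse consistency at the default regularization: the
  # reconstructed 1-9 s AUC averaged over the active region and the four
  # frequencies stays within 20% of the ground truth
  # stochastic acceptance: the regional mean recovery, averaged over the
  # four stimulation frequencies, lies within 20% of the ground truth in at
  # least 8 of 10 seeded noiseless runs
  cfg <- pipeline_config(n_subjects = 10, n_repetitions = 3,
                         noise = quiet_noise())
  ctx <- pipeline_context(cfg)
  des <- meg_design(cfg, ctx)
  act <- match(ctx$truth$regions$active$voxels, ctx$fov_voxels)
  in_band <- vapply(seq_len(cfg$n_subjects), function(s) {
    feats <- des$features[des$features$subject == s, ]
    opt <- simulate_subject_optical(cfg, ctx, feats, des$schedules[[s]],
                                    seed = s)
    ratios <- vapply(c(0.5, 1, 2, 4), function(f) {
      ff <- feats[feats$feature_id == "P35m" & feats$frequency == f, ]
      imp <- build_impulse_series(ff$value[order(ff$stimulus_index)],
                                  ctx$trains[[as.character(f)]],
                                  dt = 1 / cfg$optical_fs)
      m <- megdot:::linear_convolve(imp$n, ctx$hrf_native$h)
      tt <- (seq_along(m) - 1) / cfg$optical_fs
      sel <- tt >= 1 & tt <= 9
      true_auc <- unname(cfg$coupling["P35m"]) * trapz(tt[sel], m[sel])
      mean(opt$hbt_auc[act, match(f, opt$frequencies)]) / true_auc
    }, numeric(1))
    mean(ratios) > 0.8 && mean(ratios) < 1.2
  }, logical(1))
  expect_gte(mean(in_band), 0.8)
})

test_that("doubling all coupling weights doubles the reconstructed AUC (noise off)", {
  cfg1 <- fast_config(noise = quiet_noise(), coupling = c(P35m = 10))
  cfg2 <- fast_config(noise = quiet_noise(), coupling = c(P35m = 20))
  ctx1 <- pipeline_context(cfg1)
  ctx2 <- pipeline_context(cfg2)
  des <- meg_design(cfg1, ctx1)
  feats <- des$features[des$features$subject == 1, ]
  o1 <- simulate_subject_optical(cfg1, ctx1, feats, des$schedules[[1]], seed = 3)
  o2 <- simulate_subject_optical(cfg2, ctx2, feats, des$schedules[[1]], seed = 3)
  expect_equal(o2$hbt_auc, 2 * o1$hbt_auc, tolerance = 1e-6)
})
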