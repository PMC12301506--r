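fake_recording <- function(A_fun, nt = 600, np = 3, fs = 10) {
  t <- (seq_len(nt) - 1) / fs
  A <- matrix(A_fun(t), nt, np)
  list(time = t, fs = fs, A = list(`758` = A, `824` = A))
}

test_that("preprocessing removes constants and global gains", {
  rec <- fake_recording(function(t) 2)
  prep <- preprocess_amplitudes(rec)
  expect_lt(max(abs(prep$Y[["758"]])), 1e-8)
  rec1 <- fake_recording(function(t) 1 + 0.05 * sin(2 * pi * 0.1 * t))
  rec2 <- rec1
  rec2$A <- lapply(rec1$A, function(A) A * 3)
  p1 <- preprocess_amplitudes(rec1)
  p2 <- preprocess_amplitudes(rec2)
  expect_equal(p1$Y[["758"]], p2$Y[["758"]], tolerance = 1e-10)
})

test_that("large transients are flagged as artifacts, bad channels whole", {
  set.seed(4)
  nt <- 2000
  rec <- fake_recording(function(t) exp(rnorm(length(t), 0, 0.01)), nt = nt)
  rec$A[["758"]][, 2] <- rec$A[["758"]][, 2] *
    exp(c(rep(0, 900), rep(0.5, 30), rep(0, nt - 930)))
  prep <- preprocess_amplitudes(rec)
  expect_true(any(prep$artifact[["758"]][, 2]))
  flagged <- which(prep$artifact[["758"]][, 2])
  expect_true(all(flagged > 900 / 5 - 20 & flagged < 930 / 5 + 20))
  # non-positive amplitudes flag the whole channel
  rec$A[["758"]][10, 1] <- -1
  prep2 <- preprocess_amplitudes(rec)
  expect_true(all(prep2$artifact[["758"]][, 1]))
  expect_equal(prep2$bad_channels[["758"]], 1L)
})

test_that("FIR deconvolution recovers non-overlapping responses like epoch averaging", {
  sch <- make_run_schedule(seed = 2, n_repetitions = 2,
                           rest_range = c(30, 40))
  fs <- 2
  sch$start_time <- round(sch$start_time * fs) / fs  # on-grid block onsets
  nt <- ceiling((attr(sch, "duration") + 15) * fs)
  t <- (seq_len(nt) - 1) / fs
  shape <- function(lag) exp(-(lag - 4)^2 / 4) * (lag >= 0) * (lag <= 10.5)
  y <- numeric(nt)
  amp <- c(`0.5` = 1, `1` = 2, `2` = 3, `4` = 4)
  for (b in seq_len(nrow(sch))) {
    y <- y + amp[as.character(sch$frequency[b])] * shape(t - sch$start_time[b])
  }
  prep <- list(time = t, fs = fs,
               Y = list(`758` = matrix(y, ncol = 1)),
               artifact = list(`758` = matrix(FALSE, nt, 1)))
  fir <- average_block_responses(prep, sch)
  for (f in c(0.5, 1, 2, 4)) {
    est <- fir$responses[["758"]][as.character(f), , 1]
    expect_equal(est, amp[as.character(f)] * shape(fir$lags),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # zero signal -> zero responses
  prep$Y[["758"]][] <- 0
  fir0 <- average_block_responses(prep, sch)
  expect_lt(max(abs(fir0$responses[["758"]])), 1e-10)
})

test_that("FIR deconvolution unmixes overlapping responses exactly", {
  # dense schedule with rests shorter than the response support
  sch <- make_run_schedule(seed = 3, n_repetitions = 3, rest_range = c(5, 8))
  fs <- 2
  sch$start_time <- round(sch$start_time * fs) / fs  # on-grid block onsets
  nt <- ceiling((attr(sch, "duration") + 15) * fs)
  t <- (seq_len(nt) - 1) / fs
  shape <- function(lag, w) exp(-(lag - 3)^2 / w) * (lag >= 0) * (lag <= 10.5)
  y <- numeric(nt)
  widths <- c(`0.5` = 2, `1` = 3, `2` = 4, `4` = 5)
  for (b in seq_len(nrow(sch))) {
    lag <- t - sch$start_time[b]
    y <- y + shape(lag, widths[as.character(sch$frequency[b])])
  }
  prep <- list(time = t, fs = fs, Y = list(`758` = matrix(y, ncol = 1)),
               artifact = list(`758` = matrix(FALSE, nt, 1)))
  fir <- average_block_responses(prep, sch)
  for (f in c(0.5, 1, 2, 4)) {
    est <- fir$responses[["758"]][as.character(f), , 1]
    truth <- shape(fir$lags, widths[as.character(f)])
    expect_lt(max(abs(est - truth)), 1e-8)
  }
})

test_that("the Laplacian matches the chain example and annihilates constants", {
  L <- build_laplacian(c(1, 1, 3))
  expect_equal(as.matrix(L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  L3 <- build_laplacian(c(4, 4, 4))
  expect_true(Matrix::isSymmetric(L3))
  expect_lt(max(abs(L3 %*% rep(1, 64))), 1e-12)
  interior <- 2 + 1 * 4 + 1 * 16 + 1  # voxel (2,2,2)
  expect_equal(as.numeric(L3[interior, interior]), 6)
  ev <- eigen(as.matrix(L3), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("reconstruction is zero for zero data and shrinks with alpha", {
  inv <- small_gm_inverse()
  x0 <- reconstruct_absorption(numeric(nrow(inv$J)), inv$J, inv$L,
                               alpha = inv$alpha)
  expect_equal(max(abs(x0)), 0)
  reg <- seq(100, 140)
  xt <- numeric(ncol(inv$J)); xt[reg] <- 1e-3
  dl <- as.numeric(inv$J %*% xt)
  sol <- lapply(inv$alpha * 10^seq(-2, 6, by = 2), function(a) {
    as.numeric(reconstruct_absorption(dl, inv$J, inv$L, alpha = a))
  })
  # the penalized roughness is monotone in alpha; the norm decays to zero
  rough <- vapply(sol, function(x) {
    sqrt(sum(as.numeric(inv$L %*% x)^2) + 1e-3 * sum(x^2))
  }, numeric(1))
  expect_true(all(diff(rough) <= rough[-length(rough)] * 1e-6))
  norms <- vapply(sol, function(x) sqrt(sum(x^2)), numeric(1))
  expect_lt(norms[length(norms)], 0.05 * max(norms))
})

test_that("the returned image minimizes the quadratic objective", {
  inv <- small_gm_inverse()
  set.seed(9)
  dl <- rnorm(nrow(inv$J), 0, 1e-3)
  x <- as.numeric(reconstruct_absorption(dl, inv$J, inv$L, alpha = inv$alpha))
  obj <- tikhonov_objective(x, dl, inv$J, inv$L, inv$alpha)
  expect_lte(obj, tikhonov_objective(numeric(length(x)), dl, inv$J, inv$L,
                                     inv$alpha))
  for (i in 1:100) {
    pert <- x + rnorm(length(x), 0, sd(x) * runif(1, 0.01, 0.5))
    expect_gte(tikhonov_objective(pert, dl, inv$J, inv$L, inv$alpha), obj)
  }
})

test_that("alpha = 0 returns the minimum-norm fit with a warning when rank deficient", {
  inv <- small_gm_inverse()
  Jdup <- rbind(inv$J[1:10, ], inv$J[1, ])  # duplicated row -> rank deficient
  dl <- as.numeric(Jdup %*% replace(numeric(ncol(Jdup)), 50, 1e-3))
  expect_warning(x <- reconstruct_absorption(dl, Jdup, inv$L, alpha = 0),
                 "minimum-norm")
  expect_lt(max(abs(Jdup %*% as.numeric(x) - dl)) / max(abs(dl)), 1e-6)
})

test_that("hemoglobin conversion round-trips and preserves the HbT identity", {
  E <- hb_extinction_coefficients()
  set.seed(11)
  hbo <- rnorm(50); hbr <- rnorm(50)
  mua <- E %*% rbind(hbo, hbr)
  hb <- absorption_to_hemoglobin(mua[1, ], mua[2, ], E)
  expect_equal(as.numeric(hb$HbO2), hbo, tolerance = 1e-12)
  expect_equal(as.numeric(hb$HbR), hbr, tolerance = 1e-12)
  expect_equal(hb$HbT, hb$HbO2 + hb$HbR)
  zero <- absorption_to_hemoglobin(numeric(5), numeric(5), E)
  expect_equal(as.numeric(zero$HbT), numeric(5))
  expect_error(absorption_to_hemoglobin(1, 1, rbind(c(1, 1), c(1, 1))),
               "singular")
})

test_that("the field of view follows the threshold rule", {
  gm <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  sens <- list(list(matrix(c(0, 1, 0.01, 0.009, 0), nrow = 1)))
  fov <- compute_fov(sens, gm, threshold = 0.01)
  expect_equal(which(fov$mask), c(2, 3))
  fov0 <- compute_fov(sens, gm, threshold = 0)
  expect_equal(which(fov0$mask), which(gm))
  expect_error(compute_fov(sens, rep(FALSE, 5)), "empty gray")
  # raising the threshold never adds voxels
  prev <- sum(fov0$mask)
  for (th in c(0.001, 0.01, 0.1, 1)) {
    cur <- sum(compute_fov(sens, gm, threshold = th)$mask)
    expect_lte(cur, prev)
    prev <- cur
  }
})
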