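test_that("rigid registration recovers known transforms exactly", {
  set.seed(81)
  src <- matrix(rnorm(30, sd = 40), 10, 3)
  fit <- rigid_register(src, src)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(fit$rms, 1e-10)
  R <- rotation_matrix(c(0, 0, 30))
  tgt <- t(R %*% t(src)) + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  fit <- rigid_register(src, tgt)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, c(5, 0, 0), tolerance = 1e-8)
  expect_lt(fit$rms, 1e-8)
})

test_that("rigid registration residual tracks the correspondence noise", {
  set.seed(82)
  src <- matrix(rnorm(600, sd = 50), 200, 3)
  rms <- vapply(1:10, function(k) {
    tgt <- src + matrix(rnorm(600, sd = 1), 200, 3)
    rigid_register(src, tgt)$rms
  }, numeric(1))
  expect_equal(mean(rms), sqrt(3), tolerance = 0.15)
  expect_error(rigid_register(matrix(rep(1:3, 3), 3, 3, byrow = TRUE),
                              matrix(rnorm(9), 3, 3)), "degenerate")
})

test_that("the SRE/LRE cost matches hand-computed examples", {
  mesh <- make_ellipsoid_mesh(radii = c(60, 70, 55), n_theta = 10, n_phi = 14)
  identity_p <- list(scale = c(1, 1, 1), rotation_deg = c(0, 0, 0),
                     translation = c(0, 0, 0))
  lms <- rbind(c(0, 70, 0), c(60, 0, 0), c(0, 0, 55))
  # surface points exactly on mesh vertices, landmarks within threshold
  pts <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 7), ]
  err <- registration_error(identity_p, lms, lms + 2, mesh, pts,
                            lre_threshold = 3)
  expect_equal(err$cost, 0, tolerance = 1e-10)
  # single landmark offset below the component threshold contributes zero
  err2 <- registration_error(identity_p, lms[1, , drop = FALSE],
                             lms[1, , drop = FALSE] +
                               matrix(c(2, 0, 0), 1), mesh,
                             pts, lre_threshold = 3)
  expect_equal(err2$lre, 0)
  # offset beyond the threshold contributes the excess
  err3 <- registration_error(identity_p, lms[1, , drop = FALSE],
                             lms[1, , drop = FALSE] +
                               matrix(c(5, 0, 0), 1), mesh,
                             pts, lre_threshold = 3)
  expect_equal(err3$lre, 2)
  expect_error(registration_error(identity_p, lms[0, , drop = FALSE],
                                  lms[0, , drop = FALSE], mesh, pts),
               "empty")
})

test_that("facial points get weight 0.8 in the SRE", {
  mesh <- make_ellipsoid_mesh(radii = c(60, 70, 55), n_theta = 10, n_phi = 14)
  identity_p <- list(scale = c(1, 1, 1), rotation_deg = c(0, 0, 0),
                     translation = c(0, 0, 0))
  lms <- rbind(c(0, 70, 0), c(60, 0, 0), c(0, 0, 55))
  # two points at equal distance 10 from the surface along the z axis
  pts <- rbind(c(0, 0, 65), c(0, 0, -65))
  err <- registration_error(identity_p, lms, lms, mesh, pts,
                            facial = c(TRUE, FALSE))
  expect_equal(err$sre, (0.8 * 10 + 1 * 10) / 1.8, tolerance = 0.15)
})

test_that("point-to-mesh distance is exact for spheres", {
  mesh <- make_ellipsoid_mesh(radii = c(50, 50, 50), n_theta = 24, n_phi = 36)
  d <- point_to_mesh_distance(rbind(c(0, 0, 60), c(0, 0, 0), c(70, 0, 0)),
                              mesh)
  expect_equal(d, c(10, 50, 20), tolerance = 0.5)
})

test_that("nine-parameter search recovers a known deformation", {
  mesh <- make_ellipsoid_mesh(radii = c(60, 70, 55), n_theta = 10, n_phi = 14)
  lms <- rbind(c(0, 70, 0), c(60, 0, 0), c(-60, 0, 0), c(0, 0, 55))
  true <- list(scale = c(1.05, 1.05, 1.05), rotation_deg = c(0, 0, 5),
               translation = c(8, 0, 0))
  tgt_pts <- apply_registration(
    mesh$vertices[seq(1, nrow(mesh$vertices), by = 5), ], true)
  tgt_lms <- apply_registration(lms, true)
  fit <- optimize_registration(lms, tgt_lms, mesh, tgt_pts,
                               lre_threshold = 1, max_iter = 30)
  expect_true(all(abs(fit$scale - true$scale) <= 0.011))
  expect_true(all(abs(fit$rotation_deg - true$rotation_deg) <= 1.01))
  expect_true(all(abs(fit$translation - true$translation) <= 1.01))
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("an already-optimal start returns unchanged in one sweep", {
  mesh <- make_ellipsoid_mesh(radii = c(60, 70, 55), n_theta = 8, n_phi = 12)
  lms <- rbind(c(0, 70, 0), c(60, 0, 0), c(0, 0, 55))
  pts <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 6), ]
  ident <- list(scale = c(1, 1, 1), rotation_deg = c(0, 0, 0),
                translation = c(0, 0, 0))
  fit <- optimize_registration(lms, lms, mesh, pts, init = ident,
                               max_iter = 10)
  expect_equal(fit$scale, c(1, 1, 1))
  expect_equal(fit$translation, c(0, 0, 0))
  expect_length(fit$trace, 2)  # initial cost + one sweep without improvement
})

test_that("optode warping inverts the forward transform", {
  params <- list(scale = c(1.04, 0.97, 1.1), rotation_deg = c(3, -7, 12),
                 translation = c(5, -2, 8))
  set.seed(91)
  pos <- matrix(rnorm(30, sd = 50), 10, 3)
  fwd <- apply_registration(pos, params)
  back <- warp_optodes(params, fwd)
  expect_lt(max(abs(back - pos)), 1e-9)
  ident <- list(scale = c(1, 1, 1), rotation_deg = c(0, 0, 0),
                translation = c(0, 0, 0))
  expect_equal(warp_optodes(ident, pos), pos)
  shift <- list(scale = c(1, 1, 1), rotation_deg = c(0, 0, 0),
                translation = c(4, 0, 0))
  expect_equal(warp_optodes(shift, pos),
               pos - matrix(c(4, 0, 0), 10, 3, byrow = TRUE))
  bad <- params; bad$scale <- c(0, 1, 1)
  expect_error(apply_registration(pos, bad), "positive")
})
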