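#' Rotation matrix from Euler angles
#'
#' Composition `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` with angles in degrees.
#' @param angles_deg Length-3 numeric (roll, pitch, yaw).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (deg, roll-pitch-yaw for the Rz Ry Rx composition) from R
euler_from_rotation <- function(R) {
  pitch <- asin(pmin(pmax(-R[3, 1], -1), 1))
  roll <- atan2(R[3, 2], R[3, 3])
  yaw <- atan2(R[2, 1], R[1, 1])
  c(roll, pitch, yaw) * 180 / pi
}

#' Nine-parameter similarity transform
#'
#' Applies `x' = R %*% diag(scale) %*% x + t` to row-vector points.
#'
#' @param points N x 3 matrix.
#' @param params List with `scale` (3), `rotation_deg` (3), `translation`
#'   (3).
#' @param inverse If `TRUE` apply the inverse transform.
#' @return Transformed N x 3 matrix.
#' @export
apply_registration <- function(points, params, inverse = FALSE) {
  R <- rotation_matrix(params$rotation_deg)
  s <- params$scale
  if (any(s <= 0)) stop("scales must be positive")
  if (!inverse) {
    t(R %*% (t(points) * s)) +
      matrix(params$translation, nrow(points), 3, byrow = TRUE)
  } else {
    p0 <- points - matrix(params$translation, nrow(points), 3, byrow = TRUE)
    t((t(R) %*% t(p0)) / s)
  }
}

#' Closed-form rigid registration of corresponding point clouds
#'
#' Least-squares rotation + translation (Kabsch/Procrustes via SVD) mapping
#' `source` onto `target`, given row-wise correspondences.
#'
#' @param source,target N x 3 matrices of corresponding points (N >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (3),
#'   `rotation_deg` (Euler angles), and `rms` residual.
#' @export
rigid_register <- function(source, target) {
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 3)
  ps <- colMeans(source); pt <- colMeans(target)
  S <- sweep(source, 2, ps); Tm <- sweep(target, 2, pt)
  H <- t(S) %*% Tm
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(pt - R %*% ps)
  fitted <- t(R %*% t(source)) + matrix(tr, nrow(source), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rotation_deg = euler_from_rotation(R),
       rms = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Triangulated ellipsoid head-surface mesh (synthetic fixture)
#'
#' Latitude-longitude triangulation of an ellipsoid, used as a synthetic
#' stand-in for a meshed atlas scalp surface.
#'
#' @param radii Length-3 semi-axes in mm.
#' @param center Length-3 center in mm.
#' @param n_theta,n_phi Angular resolution (polar x azimuthal).
#' @return List with `vertices` (V x 3) and `faces` (F x 3 vertex indices).
#' @export
make_ellipsoid_mesh <- function(radii = c(80, 95, 70), center = c(0, 0, 0),
                                n_theta = 12, n_phi = 18) {
  theta <- seq(0, pi, length.out = n_theta + 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  # ring-by-ring ordering: vertex 1 + (i-1)*n_phi + j is ring i, azimuth j
  grid <- expand.grid(phi = phi, theta = theta[-c(1, n_theta + 1)])
  v <- rbind(
    c(0, 0, 1),
    cbind(sin(grid$theta) * cos(grid$phi),
          sin(grid$theta) * sin(grid$phi),
          cos(grid$theta)),
    c(0, 0, -1)
  )
  vertices <- sweep(sweep(v, 2, radii, `*`), 2, center, `+`)
  nv <- nrow(vertices)
  id <- function(i, j) 1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1]] <- c(1, id(1, j), id(1, j + 1))
    faces[[length(faces) + 1]] <- c(nv, id(n_theta - 1, j + 1), id(n_theta - 1, j))
  }
  for (i in seq_len(n_theta - 2)) {
    for (j in seq_len(n_phi)) {
      a <- id(i, j); b <- id(i, j + 1); cc <- id(i + 1, j); d <- id(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, cc)
      faces[[length(faces) + 1]] <- c(b, d, cc)
    }
  }
  list(vertices = vertices, faces = do.call(rbind, faces))
}

#' Distances from points to a triangular mesh
#'
#' Exact minimum Euclidean distance from each query point to the mesh
#' surface (closest point on each triangle found by plane projection with
#' barycentric test, falling back to the closest point on the triangle
#' edges).
#'
#' @param points N x 3 query points.
#' @param mesh List with `vertices` and `faces` (see
#'   [make_ellipsoid_mesh()]).
#' @return Numeric vector of distances (length N).
#' @export
point_to_mesh_distance <- function(points, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  AB <- B - A; AC <- C - A
  d00 <- rowSums(AB * AB); d01 <- rowSums(AB * AC); d11 <- rowSums(AC * AC)
  denom <- d00 * d11 - d01 * d01
  degenerate <- denom <= 1e-12 * pmax(d00 * d11, 1e-30)
  denom[degenerate] <- 1

  seg_dist2 <- function(P, S0, S1) {
    d <- S1 - S0
    tt <- rowSums((P - S0) * d) / pmax(rowSums(d * d), 1e-30)
    tt <- pmin(pmax(tt, 0), 1)
    rowSums((P - (S0 + d * tt))^2)
  }
  apply(points, 1, function(p) {
    P <- matrix(p, nrow(A), 3, byrow = TRUE)
    AP <- P - A
    d20 <- rowSums(AP * AB); d21 <- rowSums(AP * AC)
    v <- (d11 * d20 - d01 * d21) / denom
    w <- (d00 * d21 - d01 * d20) / denom
    inside <- v >= 0 & w >= 0 & v + w <= 1 & !degenerate
    proj <- A + AB * v + AC * w
    dist2 <- rowSums((P - proj)^2)
    if (any(!inside)) {
      i <- which(!inside)
      e <- pmin(seg_dist2(P[i, , drop = FALSE], A[i, , drop = FALSE],
                          B[i, , drop = FALSE]),
                seg_dist2(P[i, , drop = FALSE], A[i, , drop = FALSE],
                          C[i, , drop = FALSE]),
                seg_dist2(P[i, , drop = FALSE], B[i, , drop = FALSE],
                          C[i, , drop = FALSE]))
      dist2[i] <- e
    }
    sqrt(min(dist2))
  })
}

#' Combined surface and landmark registration error
#'
#' Cost of a candidate atlas-to-subject transform: the mean of the Surface
#' Registration Error (SRE) and the Landmark Registration Error (LRE).
#' LRE is the mean over landmarks of the norm of the component-wise
#' soft-thresholded differences `max(|d_c| - tau_c, 0)` (the thresholds
#' absorb the uncertainty of picking the same anatomical point twice).
#' SRE is the weighted mean distance from the target head points to the
#' warped atlas surface mesh, with weight `facial_weight` (default 0.8)
#' for facial points below the nasion and 1 otherwise.
#'
#' @param params Transform parameters (see [apply_registration()]).
#' @param atlas_landmarks,target_landmarks Corresponding K x 3 matrices.
#' @param atlas_mesh Atlas scalp mesh (warped internally by `params`).
#' @param target_head_points M x 3 digitized head-surface points.
#' @param facial Logical length-M flag for facial points.
#' @param lre_threshold Per-component threshold in mm (scalar or length 3,
#'   default 4).
#' @param facial_weight Weight of facial points in the SRE.
#' @return List with `cost`, `sre`, `lre`.
#' @export
registration_error <- function(params, atlas_landmarks, target_landmarks,
                               atlas_mesh, target_head_points,
                               facial = rep(FALSE, nrow(target_head_points)),
                               lre_threshold = 4, facial_weight = 0.8) {
  if (!nrow(atlas_landmarks) || !nrow(atlas_mesh$faces)) {
    stop("empty landmark set or mesh")
  }
  tau <- rep(lre_threshold, length.out = 3)
  wl <- apply_registration(atlas_landmarks, params)
  d <- abs(wl - target_landmarks)
  soft <- pmax(d - matrix(tau, nrow(d), 3, byrow = TRUE), 0)
  lre <- mean(sqrt(rowSums(soft^2)))

  wm <- atlas_mesh
  wm$vertices <- apply_registration(atlas_mesh$vertices, params)
  dist <- point_to_mesh_distance(target_head_points, wm)
  w <- ifelse(facial, facial_weight, 1)
  sre <- sum(w * dist) / sum(w)
  list(cost = (sre + lre) / 2, sre = sre, lre = lre)
}

#' Nine-parameter discrete registration search
#'
#' Iterative-closest-point style search over the nine parameters (three
#' scales, three rotations, three translations) on a discrete grid,
#' initialized from the closed-form rigid landmark registration (unit
#' scales). At each sweep every parameter in turn is moved by one grid step
#' in the direction that lowers the combined SRE/LRE cost (the closest
#' surface points are implicitly recomputed after every accepted
#' deformation since the full point-to-mesh distance is re-evaluated);
#' the search stops when no single-parameter step improves the cost or
#' after `max_iter` sweeps. The cost sequence is non-increasing by
#' construction.
#'
#' @inheritParams registration_error
#' @param steps Grid steps: list with `scale` (default 0.01), `rotation`
#'   (deg, default 1) and `translation` (mm, default 1).
#' @param span Search half-ranges around the initialization: `scale` 0.10,
#'   `rotation` 15 deg, `translation` 20 mm.
#' @param max_iter Maximum number of sweeps.
#' @param init Optional starting parameters; default from
#'   [rigid_register()] on the landmarks.
#' @return A `registration_params` list: `scale`, `rotation_deg`,
#'   `translation`, `cost`, `sre`, `lre` and `trace` (cost per sweep).
#' @export
optimize_registration <- function(atlas_landmarks, target_landmarks,
                                  atlas_mesh, target_head_points,
                                  facial = rep(FALSE, nrow(target_head_points)),
                                  lre_threshold = 4, facial_weight = 0.8,
                                  steps = list(scale = 0.01, rotation = 1,
                                               translation = 1),
                                  span = list(scale = 0.10, rotation = 15,
                                              translation = 20),
                                  max_iter = 50, init = NULL) {
  if (is.null(init)) {
    rig <- rigid_register(atlas_landmarks, target_landmarks)
    init <- list(scale = c(1, 1, 1), rotation_deg = rig$rotation_deg,
                 translation = rig$translation)
  }
  p <- c(init$scale, init$rotation_deg, init$translation)
  step <- c(rep(steps$scale, 3), rep(steps$rotation, 3),
            rep(steps$translation, 3))
  lo <- p - c(rep(span$scale, 3), rep(span$rotation, 3),
              rep(span$translation, 3))
  hi <- p + c(rep(span$scale, 3), rep(span$rotation, 3),
              rep(span$translation, 3))
  cost_of <- function(pv) {
    registration_error(list(scale = pv[1:3], rotation_deg = pv[4:6],
                            translation = pv[7:9]),
                       atlas_landmarks, target_landmarks, atlas_mesh,
                       target_head_points, facial, lre_threshold,
                       facial_weight)$cost
  }
  cur <- cost_of(p)
  if (!is.finite(cur)) stop("non-finite registration cost")
  trace <- cur
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (j in seq_len(9)) {
      best_p <- p; best_c <- cur
      for (dir in c(-1, 1)) {  # fixed order; ties keep the current value
        cand <- p
        cand[j] <- min(max(p[j] + dir * step[j], lo[j]), hi[j])
        if (cand[j] == p[j]) next
        cc <- cost_of(cand)
        if (cc < best_c - 1e-12) { best_c <- cc; best_p <- cand }
      }
      if (best_c < cur - 1e-12) {
        p <- best_p; cur <- best_c; improved <- TRUE
      }
    }
    trace <- c(trace, cur)
    if (!improved) break
  }
  err <- registration_error(list(scale = p[1:3], rotation_deg = p[4:6],
                                 translation = p[7:9]),
                            atlas_landmarks, target_landmarks, atlas_mesh,
                            target_head_points, facial, lre_threshold,
                            facial_weight)
  structure(list(scale = p[1:3], rotation_deg = p[4:6],
                 translation = p[7:9], cost = err$cost, sre = err$sre,
                 lre = err$lre, trace = trace),
            class = "registration_params")
}

#' Warp optode positions from the subject frame to the atlas frame
#'
#' Applies the inverse of the atlas-to-subject transform so that positions
#' measured on the subject's head are expressed in atlas coordinates.
#'
#' @param params Registration parameters (atlas -> subject).
#' @param positions N x 3 positions in the subject frame.
#' @return N x 3 positions in the atlas frame.
#' @export
warp_optodes <- function(params, positions) {
  apply_registration(positions, params, inverse = TRUE)
}
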