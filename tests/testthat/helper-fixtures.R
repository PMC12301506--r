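# Shared fixtures, built once per test run. Geometry objects are cached in
# this environment because the reconstruction operator is the only expensive
# piece of setup.
.fixtures <- new.env(parent = emptyenv())

small_head <- function() {
  if (is.null(.fixtures$head)) {
    .fixtures$head <- build_head_phantom(shape = c(20, 20, 15), voxel_size = 2)
  }
  .fixtures$head
}

small_layout <- function() {
  if (is.null(.fixtures$layout)) {
    .fixtures$layout <- build_probe_geometry(8, 8, pitch_mm = 8,
                                             center_mm = c(20, 20))
  }
  .fixtures$layout
}

small_sensitivity <- function() {
  if (is.null(.fixtures$sens)) {
    .fixtures$sens <- simulate_sensitivity(small_head(), small_layout())
  }
  .fixtures$sens
}

small_gm_inverse <- function() {
  if (is.null(.fixtures$inv)) {
    head <- small_head()
    gm <- which(head$gm_mask)
    L <- build_laplacian(head$shape, gm)
    J <- small_sensitivity()$J[[1]][, gm]
    .fixtures$inv <- list(gm = gm, L = L, J = J,
                          alpha = default_alpha(J, L, alpha_rel = 1e4))
  }
  .fixtures$inv
}

# Desk-scale pipeline configuration used by the heavier integration tests.
fast_config <- function(n_subjects = 3, n_repetitions = 3, ...) {
  pipeline_config(n_subjects = n_subjects, n_repetitions = n_repetitions,
                  n_sources = 8, n_detectors = 8, ...)
}

dice_coefficient <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Independent brute-force Pearson r and p (textbook formulas only).
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p)
}

# Brute-force flood-fill connected components on voxel indices.
bfs_components <- function(voxels, shape, connectivity = 6) {
  stopifnot(connectivity == 6)
  inset <- array(FALSE, shape)
  inset[voxels] <- TRUE
  labels <- array(0L, shape)
  cur <- 0L
  idx <- arrayInd(voxels, shape)
  for (k in seq_along(voxels)) {
    v <- voxels[k]
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- list(idx[k, ])
    labels[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in 1:3) for (s in c(-1L, 1L)) {
        q <- p; q[d] <- q[d] + s
        if (q[d] < 1 || q[d] > shape[d]) next
        lin <- q[1] + (q[2] - 1) * shape[1] + (q[3] - 1) * shape[1] * shape[2]
        if (inset[lin] && labels[lin] == 0L) {
          labels[lin] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels[voxels]
}
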