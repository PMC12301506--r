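#' Preprocess optical amplitude recordings
#'
#' Resamples each source-detector pair's amplitude to a common 2 Hz
#' timebase, takes the natural logarithm, band-pass filters from 0.01 to
#' 0.33 Hz (zero-phase Butterworth magnitude response applied in the
#' frequency domain with mirror-extended edges), and flags artifact
#' samples where the absolute filtered log-amplitude exceeds
#' `artifact_sd` times the channel's standard deviation. Channels with
#' non-positive amplitudes are flagged whole (the log is undefined).
#'
#' @param rec An `optical_recording` from [simulate_optical_run()], or any
#'   list with `A` (list per wavelength of time x pairs matrices), `fs` and
#'   `time`.
#' @param target_fs Output sampling frequency (Hz, default 2).
#' @param band Band-pass corner frequencies in Hz.
#' @param artifact_sd Artifact threshold in channel standard deviations.
#' @return List with `time`, `fs`, `Y` (list per wavelength of filtered log
#'   amplitude, time x pairs), `artifact` (logical arrays, same shape) and
#'   `bad_channels` (list per wavelength of flagged channel indices).
#' @export
preprocess_amplitudes <- function(rec, target_fs = 2, band = c(0.01, 0.33),
                                  artifact_sd = 7) {
  factor <- as.integer(round(rec$fs / target_fs))
  out_Y <- list(); out_art <- list(); bad <- list()
  for (wl in names(rec$A)) {
    A <- rec$A[[wl]]
    np <- ncol(A)
    nonpos <- which(apply(A <= 0, 2, any))
    ok <- setdiff(seq_len(np), nonpos)
    logA <- A[, ok, drop = FALSE]
    logA[] <- log(logA)
    # resample by block averaging (the boxcar suppresses out-of-band noise
    # before subsampling), then band filter on the 2 Hz timebase
    Yok <- blockmean_decimate(logA, factor)
    Yok <- fft_bandpass(Yok, target_fs, low = band[1], high = band[2],
                        order = 4)
    nt <- nrow(Yok)
    Y <- matrix(0, nt, np)
    Y[, ok] <- Yok
    art <- matrix(FALSE, nt, np)
    art[, nonpos] <- TRUE
    sds <- apply(Yok, 2, stats::sd)
    art[, ok] <- abs(Yok) > rep(artifact_sd * sds, each = nt)
    out_Y[[wl]] <- Y
    out_art[[wl]] <- art
    bad[[wl]] <- nonpos
  }
  nt_out <- nrow(out_Y[[1]])
  t2 <- rec$time[seq(1, by = factor, length.out = nt_out)]
  list(time = t2, fs = target_fs, Y = out_Y, artifact = out_art,
       bad_channels = bad)
}

#' FIR deconvolution of block-averaged hemodynamic responses
#'
#' Estimates the average response to each stimulus-train type in a window
#' from -1 to 10.5 s relative to train onset by least squares, with one
#' finite-impulse-response basis (24 taps at 2 Hz) per stimulation frequency
#' plus a shared baseline column. Overlapping responses from closely spaced
#' blocks are unmixed by the joint solve. Artifact-flagged samples are
#' excluded from the normal equations (channels sharing the same artifact
#' pattern are solved together).
#'
#' @param prep Output of [preprocess_amplitudes()].
#' @param schedule A [make_run_schedule()] object.
#' @param window Response window in seconds relative to train onset.
#' @return List with `lags` (tap times in s) and `responses`: per
#'   wavelength, a 3-d array (frequency x tap x pair). Frequencies with no
#'   usable blocks yield `NA` taps.
#' @export
average_block_responses <- function(prep, schedule, window = c(-1, 10.5)) {
  fs <- prep$fs
  lags <- seq(window[1], window[2], by = 1 / fs)
  n_taps <- length(lags)
  freqs <- sort(unique(schedule$frequency))
  nf <- length(freqs)
  nt <- length(prep$time)

  X <- matrix(0, nt, nf * n_taps + 1)
  X[, nf * n_taps + 1] <- 1
  for (b in seq_len(nrow(schedule))) {
    fi <- match(schedule$frequency[b], freqs)
    rows <- round((schedule$start_time[b] + lags) * fs) + 1
    ok <- rows >= 1 & rows <= nt
    cols <- (fi - 1) * n_taps + which(ok)
    X[cbind(rows[ok], cols)] <- X[cbind(rows[ok], cols)] + 1
  }

  responses <- list()
  for (wl in names(prep$Y)) {
    Y <- prep$Y[[wl]]
    art <- prep$artifact[[wl]]
    res <- array(NA_real_, c(nf, n_taps, ncol(Y)),
                 dimnames = list(as.character(freqs), NULL, NULL))
    sig <- apply(art, 2, function(a) paste(which(a), collapse = ","))
    for (pattern in unique(sig)) {
      ch <- which(sig == pattern)
      drop_rows <- if (nzchar(pattern))
        as.integer(strsplit(pattern, ",")[[1]]) else integer(0)
      keep <- setdiff(seq_len(nt), drop_rows)
      Xk <- X[keep, , drop = FALSE]
      used <- which(colSums(abs(Xk)) > 0)
      qrX <- qr(Xk[, used, drop = FALSE])
      if (qrX$rank < length(used)) {
        stop("rank-deficient FIR design (all blocks of a frequency rejected?)")
      }
      beta <- matrix(0, ncol(X), length(ch))
      beta[used, ] <- qr.coef(qrX, Y[keep, ch, drop = FALSE])
      for (fi in seq_len(nf)) {
        res[fi, , ch] <- beta[(fi - 1) * n_taps + seq_len(n_taps), ]
      }
    }
    responses[[wl]] <- res
  }
  list(lags = lags, frequencies = freqs, responses = responses)
}

#' Discrete negative Laplacian over the 6-neighborhood of a voxel grid
#'
#' `L[i, i]` equals the number of grid neighbors of voxel i within the
#' reconstruction domain (at most 6), `L[i, j] = -1` for neighbors, 0
#' otherwise. Symmetric, rows sum to zero, positive semidefinite; used as
#' the Tikhonov smoothing operator.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param voxels Optional integer vector of linear indices restricting the
#'   domain (for example the gray-matter voxels); the returned matrix is
#'   then the Laplacian of the induced subgraph, ordered like `voxels`.
#' @return Sparse symmetric `Matrix` of dimension `prod(shape)` (or
#'   `length(voxels)`).
#' @export
build_laplacian <- function(shape, voxels = NULL) {
  n <- prod(shape)
  idx <- arrayInd(seq_len(n), shape)
  strides <- c(1, shape[1], shape[1] * shape[2])
  from <- integer(0); to <- integer(0)
  for (ax in 1:3) {
    ok <- which(idx[, ax] < shape[ax])
    from <- c(from, ok)
    to <- c(to, ok + strides[ax])
  }
  if (!is.null(voxels)) {
    pos <- rep(NA_integer_, n)
    pos[voxels] <- seq_along(voxels)
    keep <- !is.na(pos[from]) & !is.na(pos[to])
    from <- pos[from[keep]]
    to <- pos[to[keep]]
    n <- length(voxels)
  }
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                            dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(n, deg) - A
}

#' Default regularization weight
#'
#' Scale-matching heuristic `alpha = alpha_rel * trace(J'J) / trace(L'L)`,
#' balancing the data-misfit and smoothing terms before the relative weight
#' `alpha_rel` (default 0.01) is applied.
#' @param J Sensitivity matrix (pairs x voxels).
#' @param L Laplacian from [build_laplacian()].
#' @param alpha_rel Relative regularization weight.
#' @return Scalar `alpha`.
#' @export
default_alpha <- function(J, L, alpha_rel = 0.01) {
  alpha_rel * sum(J^2) / sum(L@x^2)
}

#' Tikhonov objective value
#'
#' Evaluates `||J x - dlogA||^2 + alpha * (||L x||^2 + ridge * ||x||^2)`,
#' the quadratic objective minimized by [reconstruct_absorption()]. The
#' small `ridge` term regularizes the constant image mode on which the
#' Laplacian penalty vanishes.
#'
#' @param x Candidate absorption image (vector).
#' @param dlogA Measured log-amplitude change vector.
#' @param J,L Sensitivity matrix and Laplacian.
#' @param alpha Regularization weight.
#' @param ridge Relative zeroth-order stabilizer (default 1e-3).
#' @return Scalar objective value.
#' @export
tikhonov_objective <- function(x, dlogA, J, L, alpha, ridge = 1e-3) {
  sum((as.numeric(J %*% x) - dlogA)^2) +
    alpha * (sum(as.numeric(L %*% x)^2) + ridge * sum(x^2))
}

#' Reconstruct voxel absorption changes (Tikhonov with Laplacian prior)
#'
#' Minimizes `sum_(s,d) (J dmua - dlogA)^2 + alpha * ||L dmua||^2`
#' (stabilized by the small zeroth-order `ridge` term, see
#' [tikhonov_objective()]) by solving the normal equations
#' `(J'J + alpha (L'L + ridge I)) x = J' dlogA` exactly: a sparse Cholesky
#' factorization of the smoothing term `K = alpha (L'L + ridge I)` combined
#' with the push-through (Woodbury) identity for the low-rank data term,
#' `x = K^-1 J' (I + J K^-1 J')^-1 dlogA`. With `alpha = 0` the
#' minimum-norm least-squares solution `J'(JJ')^+ dlogA` is returned (with
#' a warning when `J` is rank deficient).
#'
#' @param dlogA Measured log-amplitude change: vector of length `nrow(J)` or
#'   a matrix with one column per time point/condition.
#' @param J Sensitivity matrix for one wavelength (pairs x voxels, mm).
#' @param L Laplacian from [build_laplacian()].
#' @param alpha Regularization weight; `NULL` uses [default_alpha()].
#' @param alpha_rel Relative weight used when `alpha` is `NULL`.
#' @param ridge Relative zeroth-order stabilizer inside the penalty.
#' @return Matrix (voxels x columns of `dlogA`) of absorption changes
#'   (mm^-1), with attribute `alpha`.
#' @export
reconstruct_absorption <- function(dlogA, J, L, alpha = NULL,
                                   alpha_rel = 0.01, ridge = 1e-3) {
  b <- as.matrix(dlogA)
  stopifnot(nrow(b) == nrow(J))
  if (is.null(alpha)) alpha <- default_alpha(J, L, alpha_rel)
  if (alpha < 0) stop("`alpha` must be non-negative")
  if (alpha == 0) {
    G <- J %*% t(J)
    sv <- svd(G)
    pos <- sv$d > max(sv$d) * 1e-12
    if (!all(pos)) warning("rank-deficient J with alpha = 0; ",
                           "returning the minimum-norm solution")
    Ginv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    x <- t(J) %*% (Ginv %*% b)
    attr(x, "alpha") <- alpha
    return(x)
  }
  R <- reconstruction_operator(J, L, alpha = alpha, ridge = ridge)
  x <- R %*% b
  attr(x, "alpha") <- alpha
  x
}

#' Precompute a linear reconstruction operator
#'
#' Returns the voxels x pairs matrix
#' `R = (J'J + alpha (L'L + ridge I))^-1 J'` so that repeated
#' reconstructions against a fixed sensitivity matrix reduce to the matrix
#' product `R %*% dlogA`. Computed exactly via a sparse Cholesky
#' factorization of the smoothing term and the push-through identity
#' `R = K^-1 J' (I + J K^-1 J')^-1` with `K = alpha (L'L + ridge I)`.
#'
#' @inheritParams reconstruct_absorption
#' @return Matrix (voxels x pairs) with attribute `alpha`.
#' @export
reconstruction_operator <- function(J, L, alpha = NULL, alpha_rel = 0.01,
                                    ridge = 1e-3) {
  if (is.null(alpha)) alpha <- default_alpha(J, L, alpha_rel)
  stopifnot(alpha > 0)
  n <- ncol(J)
  K <- alpha * (Matrix::crossprod(L) + ridge * Matrix::Diagonal(n))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE, super = TRUE)
  W <- as.matrix(Matrix::solve(ch, t(J)))          # K^-1 J'
  S <- diag(nrow(J)) + J %*% W                     # I + J K^-1 J'
  R <- W %*% solve(S)
  attr(R, "alpha") <- alpha
  R
}

#' Convert absorption changes to hemoglobin concentration changes
#'
#' Inverts the 2 x 2 extinction system per voxel:
#' `[dHbO2; dHbR] = E^-1 [dmua_758; dmua_824]`, with `dHbT` their sum.
#'
#' @param dmua_758,dmua_824 Absorption change images (vector or voxels x k
#'   matrix, mm^-1) at the two wavelengths.
#' @param E Extinction matrix from [hb_extinction_coefficients()] (rows =
#'   wavelengths, columns = HbO2, HbR; mm^-1 per micromolar).
#' @return List with `HbO2`, `HbR`, `HbT` (micromolar, same shape as input).
#' @export
absorption_to_hemoglobin <- function(dmua_758, dmua_824,
                                     E = hb_extinction_coefficients()) {
  if (abs(det(E)) < 1e-14) stop("extinction matrix is singular")
  Ei <- solve(E)
  a <- as.matrix(dmua_758); b <- as.matrix(dmua_824)
  HbO2 <- Ei[1, 1] * a + Ei[1, 2] * b
  HbR <- Ei[2, 1] * a + Ei[2, 2] * b
  list(HbO2 = HbO2, HbR = HbR, HbT = HbO2 + HbR)
}

#' Field of view from group-level measurement sensitivity
#'
#' The mean sensitivity of a voxel is the mean over source-detector pairs
#' (and wavelengths) of the absolute Jacobian entries; the group sensitivity
#' averages this over subjects. The field of view (FOV) keeps the gray
#' matter voxels whose group sensitivity is at least `threshold` (default
#' 1%) of the maximum within gray matter.
#'
#' @param sens_list List over subjects; each element a `sensitivity` object
#'   or a list of Jacobian matrices per wavelength.
#' @param gm_mask Logical array/vector marking gray matter voxels.
#' @param threshold Fraction of the GM maximum (default 0.01).
#' @return List with `mask` (logical, same shape as `gm_mask`),
#'   `sensitivity` (group mean per voxel) and `threshold`.
#' @export
compute_fov <- function(sens_list, gm_mask, threshold = 0.01) {
  stopifnot(length(sens_list) >= 1)
  if (!any(gm_mask)) stop("empty gray-matter mask")
  per_subject <- lapply(sens_list, function(s) {
    Js <- if (inherits(s, "sensitivity")) s$J else s
    if (is.matrix(Js)) Js <- list(Js)
    Reduce(`+`, lapply(Js, function(J) colMeans(abs(J)))) / length(Js)
  })
  sens <- Reduce(`+`, per_subject) / length(per_subject)
  mx <- max(sens[as.logical(gm_mask)])
  mask <- as.logical(gm_mask) & (sens >= threshold * mx)
  if (is.array(gm_mask)) mask <- array(mask, dim = dim(gm_mask))
  list(mask = mask, sensitivity = sens, threshold = threshold)
}
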