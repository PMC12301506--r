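#' Tissue optical parameters of the layered head model
#'
#' Baseline optical parameters per tissue type in the near-infrared band
#' (roughly 780-800 nm): absorption coefficient `mua` (mm^-1), scattering
#' coefficient `mus` (mm^-1), anisotropy factor `g` and refractive index `n`.
#' The values are compiled adult-head literature values.
#'
#' @return Data frame with one row per tissue label.
#' @export
tissue_optical_parameters <- function() {
  data.frame(
    tissue = c("scalp", "skull", "trabecular", "csf", "csf_sulci",
               "sss", "gm", "wm"),
    mua = c(0.0164, 0.0115, 0.016, 0.0041, 0.002, 0.3, 0.032, 0.005),
    mus = c(7.1, 9.1, 16, 2.5, 0.01, 20, 69.5, 55),
    g = c(0.9, 0.9, 0.95, 0.9, 0.9, 0.95, 0.97, 0.85),
    n = c(1.35, 1.35, 1.35, 1.35, 1.35, 1.35, 1.35, 1.35)
  )
}

#' Layered half-space head phantom
#'
#' Builds a voxelized slab phantom with horizontal tissue layers from the
#' surface downwards: scalp, skull, subarachnoid CSF, gray matter (GM), and
#' white matter (WM) filling the remainder. Voxel (i, j, k) has its center at
#' `((i-0.5), (j-0.5), (k-0.5)) * voxel_size` mm, with the third coordinate
#' measured as depth below the surface (the optode plane is depth 0).
#'
#' @param shape Integer length-3 grid dimensions (nx, ny, nz); at least
#'   20 x 20 x 15.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param layers_mm Named numeric of layer thicknesses in mm for `scalp`,
#'   `skull`, `csf` and `gm`; WM fills the rest of the grid depth.
#' @return A `head_model`: list with `shape`, `voxel_size`, `labels`
#'   (integer array, values indexing `tissues$tissue`), `tissues` (the
#'   optical parameter table restricted to the layers used), `gm_mask`
#'   (logical array) and `coords` (N x 3 matrix of voxel centers, mm).
#' @export
build_head_phantom <- function(shape = c(40, 40, 20), voxel_size = 2,
                               layers_mm = c(scalp = 6, skull = 7,
                                             csf = 2, gm = 4)) {
  stopifnot(length(shape) == 3)
  if (any(shape < c(20, 20, 15))) stop("`shape` must be at least 20 x 20 x 15")
  depth_total <- shape[3] * voxel_size
  if (sum(layers_mm) >= depth_total) {
    stop("layer thicknesses exceed the grid depth")
  }
  layer_names <- c("scalp", "skull", "csf", "gm", "wm")
  bounds <- cumsum(c(0, layers_mm[c("scalp", "skull", "csf", "gm")], Inf))
  z_centers <- (seq_len(shape[3]) - 0.5) * voxel_size
  z_label <- findInterval(z_centers, bounds, rightmost.closed = FALSE)
  labels <- array(rep(z_label, each = shape[1] * shape[2]), dim = shape)

  tissues <- tissue_optical_parameters()
  tissues <- tissues[match(layer_names, tissues$tissue), ]
  rownames(tissues) <- NULL

  gm_mask <- labels == match("gm", layer_names)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  coords <- (idx - 0.5) * voxel_size

  structure(
    list(shape = shape, voxel_size = voxel_size, labels = labels,
         layer_names = layer_names, tissues = tissues,
         gm_mask = gm_mask, coords = coords),
    class = "head_model"
  )
}

#' Volume-averaged homogeneous optical parameters of a phantom
#'
#' Averages `mua` and the reduced scattering coefficient `mus * (1 - g)` over
#' all voxels, weighting by tissue occupancy, and returns the effective
#' attenuation coefficient `mu_eff = sqrt(3 * mua * mus')` used by the
#' analytic sensitivity kernel.
#'
#' @param head A [build_head_phantom()] object.
#' @return List with `mua`, `musp` and `mu_eff` (all mm^-1).
#' @export
effective_optical_parameters <- function(head) {
  counts <- tabulate(head$labels, nbins = nrow(head$tissues))
  w <- counts / sum(counts)
  mua <- sum(w * head$tissues$mua)
  musp <- sum(w * head$tissues$mus * (1 - head$tissues$g))
  list(mua = mua, musp = musp, mu_eff = sqrt(3 * mua * musp))
}

#' High-density optode layout on the phantom surface
#'
#' Places sources and detectors on an interleaved (checkerboard) rectangular
#' grid on the top surface of the phantom and enumerates the active
#' source-detector pairs whose separation lies in `sep_range`.
#'
#' @param n_sources,n_detectors Optode counts (default 16 + 16).
#' @param pitch_mm Grid pitch between neighboring optodes in mm.
#' @param sep_range Length-2 numeric, admissible source-detector separations
#'   in mm (default 10-40 mm).
#' @param center_mm Length-2 center of the grid on the surface in mm.
#' @param grid_cols Number of grid columns; default lays the optodes out
#'   roughly 2:1 wide.
#' @return An `optode_layout`: list with `sources` and `detectors` (n x 3
#'   matrices, depth coordinate 0), `pairs` (data frame `source`, `detector`,
#'   `separation`) and `pitch_mm`.
#' @export
build_probe_geometry <- function(n_sources = 16, n_detectors = 16,
                                 pitch_mm = 10, sep_range = c(10, 40),
                                 center_mm = c(40, 40), grid_cols = NULL) {
  n <- n_sources + n_detectors
  if (is.null(grid_cols)) grid_cols <- ceiling(sqrt(2 * n))
  grid_rows <- ceiling(n / grid_cols)
  g <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  g$color <- (g$col + g$row) %% 2
  src_pos <- g[g$color == 0, ][seq_len(n_sources), ]
  det_pos <- g[g$color == 1, ][seq_len(n_detectors), ]
  if (anyNA(src_pos$col) || anyNA(det_pos$col)) {
    stop("grid too small for the requested optode counts")
  }
  to_xyz <- function(p) {
    cbind(center_mm[1] + (p$col - (grid_cols + 1) / 2) * pitch_mm,
          center_mm[2] + (p$row - (grid_rows + 1) / 2) * pitch_mm,
          0)
  }
  sources <- to_xyz(src_pos)
  detectors <- to_xyz(det_pos)

  sep <- sqrt(outer(rowSums(sources^2), rowSums(detectors^2), "+") -
                2 * sources %*% t(detectors))
  keep <- which(sep >= sep_range[1] & sep <= sep_range[2], arr.ind = TRUE)
  if (nrow(keep) == 0) stop("no source-detector pair within `sep_range`")
  pairs <- data.frame(source = keep[, 1], detector = keep[, 2],
                      separation = sep[keep])
  pairs <- pairs[order(pairs$source, pairs$detector), ]
  rownames(pairs) <- NULL
  structure(
    list(sources = sources, detectors = detectors, pairs = pairs,
         pitch_mm = pitch_mm, sep_range = sep_range),
    class = "optode_layout"
  )
}

#' Analytic diffusion sensitivity (Jacobian) matrices
#'
#' Approximates the sensitivity of each pair's log-amplitude to voxel
#' absorption changes, `J[(s,d), v] = d logA / d mua(v)`, with the normalized
#' product of isotropic diffusion kernels
#' `-G(r_s, r_v) * G(r_v, r_d) / G(r_s, r_d) * V_voxel`, where
#' `G(r) = exp(-mu_eff * r) / r` and `mu_eff = sqrt(3 * mua * mus')` comes
#' from the volume-averaged phantom parameters. All entries are non-positive
#' (an absorption increase can only decrease the detected amplitude) and the
#' kernel reproduces the characteristic banana-shaped sensitivity profile
#' between a source and a detector. Distances are floored at one voxel edge
#' to avoid the kernel singularity at an optode.
#'
#' @param head A [build_head_phantom()] object.
#' @param layout A [build_probe_geometry()] object.
#' @param wavelengths Wavelength labels in nm; one Jacobian per wavelength.
#'   The homogeneous baseline parameters are taken as wavelength-independent,
#'   so the matrices differ only by `mua_scale`.
#' @param mua_scale Optional named multiplier of the effective `mua` per
#'   wavelength (default 1 for both).
#' @param distance_floor Minimum distance in mm (default the voxel size).
#' @return A `sensitivity` object: list with `J` (list per wavelength of
#'   pairs x voxels matrices, units mm), `mu_eff`, `layout`, `head`.
#' @export
simulate_sensitivity <- function(head, layout,
                                 wavelengths = c(758, 824),
                                 mua_scale = NULL,
                                 distance_floor = head$voxel_size) {
  eff <- effective_optical_parameters(head)
  if (is.null(mua_scale)) {
    mua_scale <- rep(1, length(wavelengths))
    names(mua_scale) <- as.character(wavelengths)
  }
  vvox <- head$voxel_size^3
  coords <- head$coords
  pr <- layout$pairs
  src <- layout$sources[pr$source, , drop = FALSE]
  det <- layout$detectors[pr$detector, , drop = FALSE]

  dist_to <- function(opt) {
    # pairs x voxels matrix of distances from per-pair optode to voxel centers
    d2 <- outer(rowSums(opt^2), rowSums(coords^2), "+") - 2 * opt %*% t(coords)
    pmax(sqrt(pmax(d2, 0)), distance_floor)
  }
  rsv <- dist_to(src)
  rvd <- dist_to(det)
  rsd <- pmax(pr$separation, distance_floor)

  J <- lapply(as.character(wavelengths), function(wl) {
    mu <- sqrt(3 * eff$mua * mua_scale[[wl]] * eff$musp)
    gsv <- exp(-mu * rsv) / rsv
    gvd <- exp(-mu * rvd) / rvd
    gsd <- exp(-mu * rsd) / rsd
    -(gsv * gvd) / gsd * vvox
  })
  names(J) <- as.character(wavelengths)
  structure(
    list(J = J, mu_eff = eff$mu_eff, wavelengths = wavelengths,
         layout = layout, shape = head$shape, voxel_size = head$voxel_size),
    class = "sensitivity"
  )
}

#' Hemoglobin extinction coefficients
#'
#' Specific absorption of oxy- and deoxyhemoglobin at the two laser
#' wavelengths, expressed directly as absorption coefficient per unit
#' concentration (mm^-1 per micromolar). Derived from compiled molar
#' extinction spectra (base-10 molar extinction in cm^-1 M^-1 multiplied by
#' ln(10) and converted to mm and micromolar).
#'
#' @param wavelengths Numeric wavelengths in nm; defaults to the instrument
#'   wavelengths 758 and 824 nm.
#' @return Matrix with one row per wavelength and columns `HbO2`, `HbR`.
#' @export
hb_extinction_coefficients <- function(wavelengths = c(758, 824)) {
  # compiled molar extinction values (cm^-1 M^-1, base 10)
  tab <- rbind(`758` = c(HbO2 = 600, HbR = 1550),
               `824` = c(HbO2 = 950, HbR = 710))
  sel <- tab[as.character(wavelengths), , drop = FALSE]
  E <- sel * log(10) * 1e-6 / 10  # -> mm^-1 per uM
  rownames(E) <- as.character(wavelengths)
  E
}
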