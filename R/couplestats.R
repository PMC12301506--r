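#' Vectorized Pearson correlation of many voxels against one regressor
#'
#' Computes, for each row of `Y`, Pearson's r against `x` and the two-sided
#' p value from the t distribution with `n - 2` degrees of freedom. Voxels
#' (or a regressor) with zero variance are returned as `NA`.
#'
#' @param Y Numeric matrix, voxels x observations.
#' @param x Numeric vector, length `ncol(Y)`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_map <- function(Y, x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  stopifnot(ncol(Y) == n)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  Yc <- Y - rowMeans(Y)
  sy <- sqrt(rowSums(Yc^2))
  r <- as.numeric(Yc %*% xc) / (sy * sx)
  r[sy == 0 | sx == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Method 1: voxelwise correlation of measured response AUC with a
#' MEG-predicted AUC column
#'
#' The measured hemodynamic AUC vector `y` (one entry per subject x
#' frequency cell, per voxel) is correlated against the predicted AUCs of
#' one MEG feature (a column of the design matrix `X`).
#'
#' @param Y Matrix of measured AUCs, voxels x rows.
#' @param x Predicted AUC column for one feature (length `ncol(Y)`).
#' @param feature_id Feature label carried into the result.
#' @return A `voxel_stat_map`: list with `r`, `p`, `n`, `method`,
#'   `feature_id`.
#' @export
correlate_method1 <- function(Y, x, feature_id = NA_character_) {
  pm <- pearson_map(Y, x)
  structure(c(pm, list(method = "method1", feature_id = feature_id)),
            class = "voxel_stat_map")
}

#' Voxelwise correlation of response AUC with stimulation frequency
#'
#' As [correlate_method1()], with the regressor given by the stimulation
#' frequency of each row (in Hz by default; `log2` spacing optional).
#'
#' @param Y Matrix of measured AUCs, voxels x rows.
#' @param frequencies Stimulation frequency (Hz) of each row.
#' @param spacing `"hz"` (raw values, default) or `"log2"`.
#' @return A `voxel_stat_map` with method `"frequency"`.
#' @export
correlate_frequency <- function(Y, frequencies, spacing = c("hz", "log2")) {
  spacing <- match.arg(spacing)
  x <- if (spacing == "hz") frequencies else log2(frequencies)
  pm <- pearson_map(Y, x)
  structure(c(pm, list(method = "frequency", feature_id = "frequency")),
            class = "voxel_stat_map")
}

#' Fisher z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; correlations with
#' `|r| = 1` are clipped to 0.999999 in magnitude with a warning.
#'
#' @param r Correlation coefficient(s).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| = 1 clipped to 0.999999 before the Fisher transform")
    r <- pmin(pmax(r, -0.999999), 0.999999)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Method 2: within-subject time-course correlation with a group-level
#' Fisher z test
#'
#' For every voxel and subject, Pearson's r between the measured and
#' predicted hemodynamic samples (20 paired values: five time points at
#' 1, 3, 5, 7, 9 s for each of the four frequencies) is Fisher-transformed,
#' and a two-sided one-sample Student's t test across subjects evaluates
#' whether the mean z differs from zero. The reported voxel r is the
#' inverse Fisher transform of the mean z.
#'
#' @param measured List over subjects of voxels x samples matrices (same
#'   voxel order and sample order across subjects).
#' @param predicted Matrix subjects x samples of the MEG-predicted values.
#' @param feature_id Feature label carried into the result.
#' @return A `voxel_stat_map` with `r`, `p`, `n` (subjects), `z`
#'   (voxels x subjects) and `r_subject`.
#' @export
correlate_method2 <- function(measured, predicted,
                              feature_id = NA_character_) {
  ns <- length(measured)
  if (ns < 3) stop("need at least 3 subjects")
  stopifnot(nrow(predicted) == ns)
  nv <- nrow(measured[[1]])
  rs <- matrix(NA_real_, nv, ns)
  for (s in seq_len(ns)) {
    rs[, s] <- pearson_map(measured[[s]], predicted[s, ])$r
  }
  z <- fisher_z(rs)
  mz <- rowMeans(z)
  sdz <- apply(z, 1, stats::sd)
  tt <- mz / (sdz / sqrt(ns))
  p <- 2 * stats::pt(-abs(tt), df = ns - 1)
  structure(
    list(r = tanh(mz), p = p, n = ns, z = z, r_subject = rs,
         method = "method2", feature_id = feature_id),
    class = "voxel_stat_map"
  )
}

#' Label 6-connected (or 26-connected) components of a voxel set
#'
#' Connected-component labeling of a set of voxel linear indices on a 3-d
#' grid, via union-find over face-neighbor (or full-neighbor) adjacencies.
#'
#' @param voxels Integer vector of linear indices into the grid.
#' @param shape Grid dimensions.
#' @param connectivity 6 (face neighbors, default) or 26.
#' @return Integer vector of component labels (1-based), parallel to
#'   `voxels`.
#' @export
label_components <- function(voxels, shape, connectivity = 6) {
  k <- length(voxels)
  if (k == 0) return(integer(0))
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- arrayInd(voxels, shape)
  pos <- match(seq_len(prod(shape)), voxels)  # grid -> voxel slot (NA outside)
  offsets <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0 & (g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 |
      (g[, 2] == 0 & g[, 3] > 0)))), , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
  strides <- c(1, shape[1], shape[1] * shape[2])
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    inb <- idx[, 1] + off[1] >= 1 & idx[, 1] + off[1] <= shape[1] &
      idx[, 2] + off[2] >= 1 & idx[, 2] + off[2] <= shape[2] &
      idx[, 3] + off[3] >= 1 & idx[, 3] + off[3] <= shape[3]
    nb <- voxels[inb] + sum(off * strides)
    slot <- pos[nb]
    here <- which(inb)[!is.na(slot)]
    there <- slot[!is.na(slot)]
    for (e in seq_along(here)) {
      ra <- find(here[e]); rb <- find(there[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

#' Form clusters of subthreshold voxels at multiple p thresholds
#'
#' At each voxel-level threshold (defaults L1 p < 0.001, L2 p < 0.003,
#' L3 p < 0.01), adjacent subthreshold voxels are merged into 6-connected
#' clusters; clusters smaller than `min_volume` (default 50 mm^3) are
#' discarded. The cluster statistic is recomputed by averaging the member
#' voxels' signals and rerunning the correlation test (`stat_fun`). When
#' clusters found at different thresholds overlap spatially, the level with
#' the lowest cluster p value is reported for that spatial component.
#'
#' @param stat_map A `voxel_stat_map` defined on the field of view.
#' @param fov_voxels Integer linear indices of the voxels the map is
#'   defined on (parallel to `stat_map$r`).
#' @param shape Grid dimensions.
#' @param voxel_size Voxel edge length in mm.
#' @param stat_fun Function of a vector of member positions (indices into
#'   `fov_voxels`) returning `list(r =, p =)` for the averaged signal.
#' @param min_volume Minimum cluster volume in mm^3.
#' @param levels Named vector of voxel p thresholds.
#' @param connectivity Neighborhood for merging (6, matching the Laplacian).
#' @param select `"best_level"` (default; one row per spatial component) or
#'   `"all"` (every surviving cluster at every level).
#' @return Data frame with columns `level`, `n_voxels`, `volume_mm3`, `r`,
#'   `p` and a list column `voxels` (grid linear indices); zero rows when
#'   nothing survives.
#' @export
form_clusters <- function(stat_map, fov_voxels, shape, voxel_size,
                          stat_fun, min_volume = 50,
                          levels = c(L1 = 0.001, L2 = 0.003, L3 = 0.01),
                          connectivity = 6,
                          select = c("best_level", "all")) {
  select <- match.arg(select)
  vvol <- voxel_size^3
  out <- list()
  for (lev in names(levels)) {
    sub <- which(!is.na(stat_map$p) & stat_map$p < levels[[lev]])
    if (!length(sub)) next
    lab <- label_components(fov_voxels[sub], shape, connectivity)
    for (cl in unique(lab)) {
      members <- sub[lab == cl]
      vol <- length(members) * vvol
      if (vol < min_volume) next
      st <- stat_fun(members)
      out[[length(out) + 1]] <- data.frame(
        level = lev, n_voxels = length(members), volume_mm3 = vol,
        r = st$r, p = st$p
      )
      out[[length(out)]]$voxels <- list(fov_voxels[members])
    }
  }
  if (!length(out)) {
    return(data.frame(level = character(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), r = numeric(0),
                      p = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (select == "all" || nrow(res) == 1) return(res)

  # group spatially overlapping clusters across levels, keep lowest p
  ncl <- nrow(res)
  parent <- seq_len(ncl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(ncl - 1)) {
    for (b in (a + 1):ncl) {
      if (length(intersect(res$voxels[[a]], res$voxels[[b]]))) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  groups <- vapply(seq_len(ncl), find, integer(1))
  keep <- vapply(unique(groups), function(g) {
    cand <- which(groups == g)
    cand[which.min(res$p[cand])]
  }, integer(1))
  res <- res[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bonferroni correction of cluster p values
#'
#' Multiplies cluster p values by the number of independently imageable
#' regions (`n_mc = 187` by default, estimated from the average number of
#' source-detector pairs) and clips at 1. Clusters are flagged for
#' reporting at corrected p < 0.2 and as significant at p < 0.05.
#'
#' @param clusters Data frame from [form_clusters()].
#' @param n_mc Bonferroni multiplier.
#' @param report_threshold,sig_threshold Reporting and significance cutoffs
#'   on the corrected p value.
#' @return The data frame with `p_corrected`, `reported` and `significant`
#'   columns added.
#' @export
correct_clusters <- function(clusters, n_mc = 187, report_threshold = 0.2,
                             sig_threshold = 0.05) {
  if (!nrow(clusters)) {
    clusters$p_corrected <- numeric(0)
    clusters$reported <- logical(0)
    clusters$significant <- logical(0)
    return(clusters)
  }
  clusters$p_corrected <- pmin(1, clusters$p * n_mc)
  clusters$reported <- clusters$p_corrected < report_threshold
  clusters$significant <- clusters$p_corrected < sig_threshold
  clusters
}

#' Permutation test for a subgroup difference in correlation
#'
#' Tests whether the correlation between a cluster signal `y` and regressor
#' `x` differs between two subject subgroups (for example, two recording
#' systems). The statistic is `|r_A - r_B|`, recomputed under random
#' reassignments of subjects to groups of the original sizes;
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param y,x Numeric vectors (one entry per observation row).
#' @param subject Subject identifier per row.
#' @param group Named assignment of each subject to one of two groups
#'   (vector parallel to `unique(subject)`, or named by subject).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `perm` (the permuted statistics).
#' @export
subgroup_permutation_test <- function(y, x, subject, group, n_perm = 1000,
                                      seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  subjects <- unique(subject)
  if (is.null(names(group))) names(group) <- subjects
  glev <- unique(group)
  if (length(glev) != 2) stop("exactly two groups required")
  sizes <- table(factor(group, levels = glev))
  if (any(sizes < 2)) stop("each group must contain at least 2 subjects")

  stat <- function(assign) {
    ga <- names(assign)[assign == glev[1]]
    gb <- names(assign)[assign == glev[2]]
    ra <- stats::cor(y[subject %in% ga], x[subject %in% ga])
    rb <- stats::cor(y[subject %in% gb], x[subject %in% gb])
    abs(ra - rb)
  }
  observed <- stat(group)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(group)
    names(g) <- names(group)
    stat(g)
  }, numeric(1))
  list(p = (1 + sum(perm >= observed)) / (1 + n_perm),
       observed = observed, perm = perm)
}

#' Calibrate the minimum cluster volume against a null ensemble
#'
#' Given, for each null dataset, the maximum volume (mm^3) of any cluster
#' that passes the voxel-level threshold (0 when no voxel survives), picks
#' the smallest minimum-volume rule for which the fraction of null datasets
#' with a surviving cluster does not exceed `target_fpr`.
#'
#' @param max_null_volumes Numeric vector, one value per null dataset.
#' @param target_fpr Target family-wise false-positive rate (default 0.05).
#' @param voxel_volume Voxel volume in mm^3 (the calibration step size).
#' @return List with `min_volume` (mm^3) and `fpr_estimate` (achieved rate
#'   on the calibration ensemble).
#' @export
calibrate_min_volume <- function(max_null_volumes, target_fpr = 0.05,
                                 voxel_volume = 8) {
  stopifnot(length(max_null_volumes) >= 20)
  cand <- sort(unique(c(0, max_null_volumes))) + voxel_volume
  fpr <- vapply(cand, function(v) mean(max_null_volumes >= v), numeric(1))
  ok <- which(fpr <= target_fpr)
  v <- cand[ok[1]]
  list(min_volume = v, fpr_estimate = mean(max_null_volumes >= v))
}
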