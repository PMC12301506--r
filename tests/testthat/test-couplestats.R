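test_that("vectorized Pearson maps match cor.test and the textbook formula", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    Y <- matrix(rnorm(10 * n), 10, n)
    pm <- pearson_map(Y, x)
    for (v in c(1, 5, 10)) {
      ct <- cor.test(Y[v, ], x)
      expect_equal(pm$r[v], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(pm$p[v], ct$p.value, tolerance = 1e-12)
      oracle <- pearson_oracle(Y[v, ], x)
      expect_equal(pm$r[v], oracle$r, tolerance = 1e-12)
      expect_equal(pm$p[v], oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("Pearson map handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  Y <- rbind(2 * x + 1, -x, rep(5, 4), c(1, 3, 2, 5))
  pm <- pearson_map(Y, x)
  expect_equal(pm$r[1], 1)
  expect_equal(pm$r[2], -1)
  expect_true(is.na(pm$r[3]))
  expect_equal(pearson_map(matrix(c(1, 2, 3), 1), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_map(matrix(1:2, 1), 1:2), "at least 3")
})

test_that("the Fisher transform matches its closed form and clips |r| = 1", {
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_lt(z, Inf)
})

test_that("Method 2 recovers coupled samples and is calibrated under the null", {
  set.seed(31)
  ns <- 8; nv <- 400
  pred <- matrix(rnorm(ns * 20), ns)
  # null: measured independent of predictions
  measured <- lapply(1:ns, function(s) matrix(rnorm(nv * 20), nv))
  null_map <- correlate_method2(measured, pred)
  ks <- suppressWarnings(ks.test(null_map$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # coupled voxels reach low p
  coupled <- lapply(1:ns, function(s) {
    matrix(rep(pred[s, ], each = 5), 5) + matrix(rnorm(5 * 20, 0, 0.3), 5)
  })
  alt_map <- correlate_method2(coupled, pred)
  expect_true(all(alt_map$p < 0.01))
  expect_true(all(alt_map$r > 0.5))
})

test_that("frequency correlation uses the Hz values", {
  rows <- rep(c(0.5, 1, 2, 4), 3)
  Y <- unname(rbind(rows, -rows, rnorm(12)))
  map <- correlate_frequency(Y, rows)
  expect_equal(map$r[1], 1)
  expect_equal(map$r[2], -1)
  maplog <- correlate_frequency(Y, rows, spacing = "log2")
  expect_equal(maplog$r[1], cor(log2(rows), rows))
})

test_that("component labeling agrees with a brute-force flood fill", {
  set.seed(41)
  shape <- c(10, 10, 10)
  for (rep in 1:50) {
    vox <- sort(sample(prod(shape), sample(30:200, 1)))
    lab <- label_components(vox, shape)
    ref <- bfs_components(vox, shape)
    # same partition: labels equal up to renaming
    expect_equal(length(unique(lab)), length(unique(ref)))
    expect_true(all(tapply(ref, lab, function(v) length(unique(v))) == 1))
  }
  expect_equal(label_components(integer(0), shape), integer(0))
})

test_that("26-connectivity merges diagonal neighbors, 6 does not", {
  shape <- c(5, 5, 5)
  vox <- c(1, 1 + 1 + 5)  # diagonal in the xy plane
  expect_equal(length(unique(label_components(vox, shape, 6))), 2)
  expect_equal(length(unique(label_components(vox, shape, 26))), 1)
})

test_that("clusters respect thresholds, minimum volume and report the best level", {
  shape <- c(6, 6, 3)
  fov <- seq_len(prod(shape))
  p <- rep(0.5, length(fov))
  blob <- c(1, 2, 7, 8)          # 2x2 block in the first slice
  p[blob] <- 1e-4
  pair <- c(29, 30)              # two adjacent voxels elsewhere
  p[pair] <- 0.005
  map <- structure(list(r = 1 - p, p = p, n = 10), class = "voxel_stat_map")
  stat_fun <- function(members) list(r = 0.9, p = min(p[members]))
  cl <- form_clusters(map, fov, shape, voxel_size = 2, stat_fun,
                      min_volume = 16)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$voxels[[which.max(cl$n_voxels)]], blob)
  # the blob is found at every level; the reported level has the lowest p
  expect_true(all(cl$level %in% c("L1", "L2", "L3")))
  # minimum volume: the 16 mm^3 pair is rejected by a 20 mm^3 rule
  one <- form_clusters(map, fov, shape, voxel_size = 2, stat_fun,
                       min_volume = 20)
  expect_true(all(one$volume_mm3 >= 20))
  expect_false(any(vapply(one$voxels, function(v) setequal(v, pair),
                          logical(1))))
  # nothing subthreshold -> empty result
  p2 <- rep(0.5, length(fov))
  map2 <- structure(list(r = 1 - p2, p = p2, n = 10),
                    class = "voxel_stat_map")
  expect_equal(nrow(form_clusters(map2, fov, shape, 2, stat_fun)), 0)
})

test_that("clustering at one level matches an igraph components oracle", {
  skip_if_not_installed("igraph")
  set.seed(53)
  shape <- c(8, 8, 4)
  vox <- sort(sample(prod(shape), 80))
  lab <- label_components(vox, shape)
  idx <- arrayInd(vox, shape)
  edges <- NULL
  for (a in seq_along(vox)) {
    for (b in seq_along(vox)) {
      if (a < b && sum(abs(idx[a, ] - idx[b, ])) == 1) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(vox) - igraph::vcount(g))
  ref <- igraph::components(g)$membership
  expect_equal(length(unique(lab)), igraph::components(g)$no)
  expect_true(all(tapply(ref, lab, function(v) length(unique(v))) == 1))
})

test_that("Bonferroni correction multiplies, clips, and flags", {
  cl <- data.frame(level = c("L1", "L3", "L2"),
                   n_voxels = c(10, 5, 8), volume_mm3 = c(80, 40, 64),
                   r = c(0.8, 0.5, 0.6), p = c(1e-4, 0.01, 1e-3))
  out <- correct_clusters(cl, n_mc = 187)
  expect_equal(out$p_corrected, c(0.0187, 1, 0.187))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$reported, c(TRUE, FALSE, TRUE))
  expect_true(all(out$p_corrected >= out$p))
  ident <- correct_clusters(cl, n_mc = 1)
  expect_equal(ident$p_corrected, cl$p)
  empty <- correct_clusters(cl[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_corrected", "significant") %in% names(empty)))
})

test_that("the subgroup permutation test is valid and bounded", {
  set.seed(61)
  subj <- rep(1:8, each = 4)
  x <- rnorm(32)
  y <- 0.5 * x + rnorm(32)
  gp <- setNames(rep(c("A", "B"), each = 4), 1:8)
  pt <- subgroup_permutation_test(y, x, subj, gp, n_perm = 199, seed = 3)
  expect_gte(pt$p, 1 / 200)
  expect_lte(pt$p, 1)
  # exchangeable data: p roughly uniform over replicates
  ps <- vapply(1:40, function(k) {
    yk <- rnorm(32)
    subgroup_permutation_test(yk, x, subj, gp, n_perm = 99, seed = k)$p
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
  expect_error(subgroup_permutation_test(y, x, subj, gp, n_perm = 0), "n_perm")
  bad <- setNames(c("A", rep("B", 7)), 1:8)
  expect_error(subgroup_permutation_test(y, x, subj, bad), "at least 2")
})

test_that("minimum-volume calibration hits the target rate", {
  set.seed(71)
  maxvol <- c(rep(0, 150), runif(50, 8, 400))
  cal <- calibrate_min_volume(maxvol, target_fpr = 0.05, voxel_volume = 8)
  expect_lte(cal$fpr_estimate, 0.05)
  expect_gte(cal$fpr_estimate, 0.02)
  expect_equal(mean(maxvol >= cal$min_volume), cal$fpr_estimate)
})
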