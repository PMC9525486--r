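# sphere construction, cluster labelling, nearest-CAF distance fields,
# L_mean and scale calibration

test_that("locked sphere convention reproduces the printed voxel count", {
  m <- build_spherical_mask(3000, 20)
  expect_identical(sum(m$mask), 1767063L)
  # within 0.05% of the continuum volume (pi/6) d^3 / spacing^3
  expect_lt(abs(sum(m$mask) - pi / 6 * 150^3) / (pi / 6 * 150^3), 5e-4)
  # the other conventions do NOT reproduce it (the lock matters)
  expect_false(sum(build_spherical_mask(3000, 20, inclusive = FALSE)$mask) == 1767063L)
  expect_false(sum(build_spherical_mask(3000, 20, "corner")$mask) == 1767063L)
})

test_that("degenerate spheres behave", {
  expect_identical(sum(build_spherical_mask(20, 20)$mask), 1L)
  expect_error(build_spherical_mask(-5, 20))
})

test_that("cluster labels honour the tumor fraction exactly and reproducibly", {
  mask <- fx_small_sphere()
  for (morph in c("interspersed-cubes", "blob-field", "few-large-blobs", "shell")) {
    v <- generate_cluster_labels(mask, cluster_spec(morph, 150, seed = 3))
    expect_true(all(v$labels %in% 0:2))
    expect_lt(abs(tumor_fraction(v) - 0.75), 0.005)
    v2 <- generate_cluster_labels(mask, cluster_spec(morph, 150, seed = 3))
    expect_identical(v$labels, v2$labels)
    v3 <- generate_cluster_labels(mask, cluster_spec(morph, 150, seed = 4))
    expect_false(identical(v$labels, v3$labels))
  }
  expect_error(cluster_spec("shell", 150, tumor_fraction = 1), "tumor_fraction")
})

test_that("axis-raycast distances match hand enumeration", {
  # 1D row [T, T, C]: the first tumor voxel is 2 steps from the CAF, the
  # second 1 step
  L <- array(2L, c(3, 1, 1)); L[1:2, 1, 1] <- 1L
  f <- compute_nearest_caf_distances(L, spacing = 20)
  expect_equal(f$distance_um[1:2, 1, 1], c(40, 20))
  expect_true(is.na(f$distance_um[3, 1, 1]))  # CAF voxels carry no distance

  # face adjacency gives one step
  L <- array(1L, c(3, 3, 3)); L[2, 2, 3] <- 2L
  f <- compute_nearest_caf_distances(L, spacing = 20)
  expect_equal(f$distance_um[2, 2, 2], 20)
  # the center voxel of an all-tumor cube with a corner CAF has no axis hit
  L <- array(1L, c(3, 3, 3)); L[1, 1, 1] <- 2L
  f <- compute_nearest_caf_distances(L, spacing = 20)
  expect_true(f$undefined[2, 2, 2])
  expect_true(is.na(f$distance_um[2, 2, 2]))
  # rays do not cross outside voxels
  L <- array(0L, c(3, 1, 1)); L[1:3, 1, 1] <- c(1L, 0L, 2L)
  f <- compute_nearest_caf_distances(L, spacing = 20)
  expect_true(f$undefined[1, 1, 1])

  expect_error(compute_nearest_caf_distances(array(1L, c(3, 3, 3))), "no CAF")
})

test_that("stripe fixtures reproduce hand-enumerated L_means", {
  # one-sided CAF sheet: column 1 CAF, columns 2..4 tumor -> distances 1..3
  # steps, mean (w+1)/2 = 2 steps = 40 um
  L <- matrix(1L, 4, 4); L[, 1] <- 2L
  f <- compute_nearest_caf_distances(L, spacing = 20)
  expect_equal(l_mean(f), 20 * (3 + 1) / 2)
  # periodic two-sided stripes (width 3, CAF every 4th plane), size 16:
  # interior stripes contribute {1,2,1}, the leading edge stripe {3,2,1};
  # overall mean = (6 + 3*4) / 12 steps = 1.5 steps = 30 um
  f <- compute_nearest_caf_distances(fx_stripes())
  expect_equal(l_mean(f), 30)
  # every distance is a positive multiple of the spacing
  d <- f$distance_um[is.finite(f$distance_um)]
  expect_true(all(d %% 20 == 0 & d >= 20))
  # checkerboard: every tumor voxel face-adjacent to CAF
  expect_equal(l_mean(compute_nearest_caf_distances(
    make_toy_labelmap("checkerboard", size = 8))), 20)
})

test_that("l_mean averages defined distances only", {
  f <- list(distance_um = c(40, 20, NA), undefined = c(FALSE, FALSE, TRUE))
  class(f) <- "lfield"
  expect_equal(l_mean(f), 30)
  f0 <- list(distance_um = c(NA_real_), undefined = TRUE)
  class(f0) <- "lfield"
  expect_error(l_mean(f0), "undefined")
})

test_that("directional-mean variant is bounded below by the nearest-ray L", {
  v <- generate_cluster_labels(fx_small_sphere(),
                               cluster_spec("blob-field", 120, seed = 5))
  lmin <- l_mean(compute_nearest_caf_distances(v))
  lmea <- l_mean(compute_nearest_caf_distances(v, combine = "mean"))
  expect_gt(lmea, lmin)
})

test_that("L_mean grows with clustering scale and is seed-stable", {
  mask <- fx_small_sphere()
  scales <- c(60, 100, 150, 220, 320)
  lm <- vapply(scales, function(s) l_mean(compute_nearest_caf_distances(
    generate_cluster_labels(mask, cluster_spec("interspersed-cubes", s,
                                               seed = 2)))), 0)
  # non-decreasing up to sub-voxel discretization jitter
  expect_true(all(diff(lm) > -0.02 * mean(lm)))
  expect_gt(lm[5], lm[1])
  # seed perturbs the lattice offset only: L_mean stable within ~3%
  lms <- vapply(1:4, function(sd) l_mean(compute_nearest_caf_distances(
    generate_cluster_labels(mask, cluster_spec("interspersed-cubes", 150,
                                               seed = sd)))), 0)
  expect_lt((max(lms) - min(lms)) / mean(lms), 0.06)
})

test_that("scale calibration reaches feasible targets and refuses others", {
  mask <- fx_small_sphere()
  spec <- calibrate_scale_to_lmean(mask, "interspersed-cubes", 60, seed = 2)
  expect_lt(abs(attr(spec, "achieved_lmean") - 60) / 60, 0.02)
  v <- generate_cluster_labels(mask, spec)
  expect_lt(abs(l_mean(compute_nearest_caf_distances(v)) - 60) / 60, 0.02)

  expect_error(calibrate_scale_to_lmean(mask, "interspersed-cubes", 10),
               "below the voxel spacing")
  expect_error(calibrate_scale_to_lmean(mask, "interspersed-cubes", 5000),
               "unreachable")
})
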