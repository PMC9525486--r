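# DVH curves, efficacy ratios, threshold fractions, pairing reports

test_that("cumulative DVH is a correct step/monotone curve", {
  lab <- fx_stripes()
  tgt <- lab$labels == 1L
  d <- array(2.5, dim(lab$labels))
  dvh <- cumulative_dvh(d, tgt, n_bins = 64)
  expect_equal(dvh$volume_pct[1], 100)
  expect_true(all(dvh$volume_pct[dvh$dose_Gy <= 2.5] == 100))
  expect_true(all(diff(dvh$volume_pct) <= 0))
  # scale equivariance: doubling dose and edges leaves the curve unchanged
  set.seed(2)
  d2 <- array(runif(prod(dim(lab$labels))), dim(lab$labels))
  a <- cumulative_dvh(d2, tgt, 128)
  b <- cumulative_dvh(d2 * 2, tgt, 128)
  expect_equal(a$volume_pct, b$volume_pct)
  expect_equal(b$dose_Gy, a$dose_Gy * 2)
  expect_error(cumulative_dvh(d2, array(FALSE, dim(d2))), "empty")
})

test_that("zero-range and flat kernels give the analytic efficacy-ratio limits", {
  lab <- fx_stripes()             # exact 75/25 tumor/CAF, no outside voxels
  sm <- lab$labels != 0L
  caf <- lab$labels == 2L
  tum <- lab$labels == 1L
  act <- build_activity_map(lab, "caf", 1e6)
  # zero-range (delta) kernel: all energy stays in the CAF sources
  d_delta <- convolve_superposition(act, make_test_kernel("delta", 5))
  expect_equal(efficacy_ratio(d_delta, caf, sm), 4.0, tolerance = 1e-9)
  expect_equal(efficacy_ratio(d_delta, tum, sm), 0.0)
  # flat kernel spanning the whole domain: perfectly uniform dose, all ERs 1
  d_flat <- convolve_superposition(act, make_test_kernel("flat", 33))
  expect_lt(abs(efficacy_ratio(d_flat, caf, sm) - 1), 1e-6)
  expect_lt(abs(efficacy_ratio(d_flat, tum, sm) - 1), 1e-6)
  expect_error(efficacy_ratio(d_flat, caf, array(FALSE, dim(caf))), "empty")
})

test_that("volume-weighted ER identity holds for any dose and source", {
  lab <- fx_stripes()
  sm <- lab$labels != 0L
  set.seed(31)
  d <- array(stats::rexp(prod(dim(lab$labels))), dim(lab$labels))
  er_c <- efficacy_ratio(d, lab$labels == 2L, sm)
  er_t <- efficacy_ratio(d, lab$labels == 1L, sm)
  expect_lt(abs(0.25 * er_c + 0.75 * er_t - 1), 1e-6)
})

test_that("threshold fraction uses the whole-mass maximum", {
  lab <- fx_stripes()
  tgt <- lab$labels == 1L
  sm <- lab$labels != 0L
  d <- array(1, dim(lab$labels))
  expect_equal(fraction_above_relative_threshold(d, tgt, sm), 100)
  d0 <- array(0, dim(lab$labels))
  one <- which(tgt)[1]
  d0[one] <- 5
  expect_equal(fraction_above_relative_threshold(d0, tgt, sm),
               100 / sum(tgt))
  # a hot voxel outside the target raises the threshold for the target
  d1 <- array(1, dim(lab$labels))
  d1[which(lab$labels == 2L)[1]] <- 1000
  expect_equal(fraction_above_relative_threshold(d1, tgt, sm), 0)
  # winsorized maximum ignores a single outlier voxel (needs enough voxels
  # for the 99.99th percentile to fall below the outlier)
  big <- array(1, c(32, 32, 32)); big[1] <- 1000
  all32 <- array(TRUE, c(32, 32, 32))
  expect_lt(fraction_above_relative_threshold(big, all32, all32), 0.01)
  expect_equal(fraction_above_relative_threshold(big, all32, all32,
                                                 winsorize = TRUE), 100)
  expect_error(fraction_above_relative_threshold(d0 * 0, tgt, sm), "all-zero")
})

test_that("pairing analysis emits six consistent reports", {
  lab <- fx_stripes()
  act_t <- build_activity_map(lab, "tumor", 1e6)
  act_c <- build_activity_map(lab, "caf", 1e6)
  k <- make_test_kernel("gaussian", 7, sigma_vox = 1)
  dt <- convolve_superposition(act_t, k)
  dc <- convolve_superposition(act_c, k)
  reps <- analyze_pairings(lab, dt, dc, "test", 1e6)
  expect_length(reps, 6L)
  expect_named(reps, c("tumor<-tumor", "caf<-tumor", "tumor<-caf",
                       "caf<-caf", "sm<-tumor", "sm<-caf"))
  # whole-mass target has ER 1 by construction
  expect_equal(reps[["sm<-tumor"]]$er, 1)
  expect_equal(reps[["sm<-caf"]]$er, 1)
  # volume-weighted decomposition per source
  expect_lt(abs(0.25 * reps[["caf<-caf"]]$er +
                0.75 * reps[["tumor<-caf"]]$er - 1), 1e-6)
  sumdf <- pairing_summary(reps)
  expect_equal(nrow(sumdf), 6L)
  bad <- dt; bad$dose_Gy <- array(0, c(4, 4, 4))
  expect_error(analyze_pairings(lab, bad, dc, "test", 1e6), "grid")
})
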