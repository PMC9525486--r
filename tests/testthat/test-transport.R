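# straight-track CSDA Monte Carlo engine: single-track deposition, alpha-chain
# simulation, electron kernel generation

test_that("a short track deposits its full energy in one voxel", {
  tal <- array(0, c(5, 5, 5))
  spe <- fx_spt_e()
  # 10 keV electron: range ~2.5 um, well inside one 20 um voxel
  r <- deposit_track(tal, 20, c(50, 50, 50), c(1, 0, 0), 0.01, spe)
  expect_lt(abs(sum(r$tally) - r$emitted) / r$emitted, 1e-12)
  expect_equal(r$escaped, 0)
  expect_gt(r$tally[3, 3, 3], 0)
  expect_equal(sum(r$tally > 0), 1L)
  expect_lt(abs(r$emitted - 0.01) / 0.01, 1e-3)  # table lookup consistency
})

test_that("a track leaving the grid books the remainder as escaped", {
  tal <- array(0, c(5, 5, 5))
  r <- deposit_track(tal, 20, c(99.9, 50, 50), c(1, 0, 0), 5, fx_spt_a())
  expect_lt(abs(r$deposited + r$escaped - r$emitted) / r$emitted, 1e-12)
  expect_gt(r$escaped, 0)
  # pointing outward from the very edge: everything escapes
  tal2 <- array(0, c(5, 5, 5))
  r2 <- deposit_track(tal2, 20, c(99.5, 50, 50), c(1, 0, 0), 8, fx_spt_a())
  expect_equal(sum(r2$tally), r2$deposited)
  expect_gt(r2$escaped / r2$emitted, 0.95)
  expect_error(deposit_track(tal, 20, c(50, 50, 50), c(0, 0, 0), 5, fx_spt_a()),
               "unit length")
})

test_that("axis-aligned alpha deposition shows a Bragg peak and matches a fine-step oracle", {
  spa <- fx_spt_a()
  tal <- array(0, c(9, 3, 3))
  r <- deposit_track(tal, 20, c(10, 30, 30), c(1, 0, 0), 8, spa, density = 1.05,
                     cfg = transport_config(step_length_um = 2))
  prof <- r$tally[, 2, 2]
  # oracle: 0.1 um steps through the residual-energy curve, binned per voxel
  s <- seq(0, csda_range(spa, 8, 1.05), by = 0.1)
  Eres <- residual_energy(spa, 8, s, 1.05)
  dE <- -diff(Eres)
  xmid <- 10 + (head(s, -1) + tail(s, -1)) / 2
  oracle <- vapply(1:9, function(i)
    sum(dE[xmid >= (i - 1) * 20 & xmid < i * 20]), 0)
  expect_lt(max(abs(prof - oracle)) / max(oracle), 0.02)
  # Bragg peak: the last substantially hit voxel receives the most energy
  expect_gt(which.max(prof), 1)
  expect_equal(which.max(prof), which.max(oracle))
})

test_that("alpha-chain simulation conserves energy and matches the scheme expectation", {
  # single-voxel source in the middle of a grid large enough that no track exits
  lab <- array(1L, c(13, 13, 13))
  lab[7, 7, 7] <- 2L
  vol <- structure(list(labels = lab, grid = grid_spec(20, dim(lab), "center"),
                        density = 1.05, provenance = list()),
                   class = "label_volume")
  ac <- fx_ac()
  set.seed(11)
  dep <- simulate_mc_dose(vol, "caf", 4000, ac,
                          cfg = transport_config(include_chain_electrons = FALSE))
  expect_lt(abs(dep$deposited_MeV + dep$escaped_MeV - dep$emitted_MeV) /
              dep$emitted_MeV, 1e-9)
  al <- ac$alpha_lines
  expected <- sum(al$energy_MeV * al$yield) +          # alphas
    sum(al$energy_MeV * al$yield * 4 / al$A_daughter)  # local recoils
  # electron range far exceeds the 13-voxel box, so compare alphas+recoils only
  expect_lt(abs(dep$emitted_MeV / dep$n_decays - expected) / expected, 0.01)
  # alpha locality: the chain stops within ~100 um of the source voxel
  ai <- arrayInd(which(dep$tally_MeV > 0), dim(lab))
  d_um <- sqrt(rowSums((sweep(ai, 2, c(7, 7, 7)) * 20)^2))
  inside <- d_um <= 120
  expect_gt(sum(dep$tally_MeV[dep$tally_MeV > 0][inside]) / dep$deposited_MeV,
            0.999)
})

test_that("kernel totals are converged in the track step length", {
  sch <- fx_lu()
  totals <- vapply(c(1, 2, 4), function(st) {
    set.seed(55)
    k <- generate_beta_kernel(sch, shape = 61, primaries = 2e4, n_batches = 4,
                              symmetrize = FALSE,
                              cfg = transport_config(step_length_um = st))
    sum(k$values)
  }, 0)
  expect_lt(abs(totals[1] - totals[2]) / totals[2], 0.01)
  expect_lt(abs(totals[3] - totals[2]) / totals[2], 0.01)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  vol <- make_toy_labelmap("checkerboard", size = 10)
  ac <- fx_ac()
  set.seed(5); a <- simulate_alpha_dose(vol, "caf", 2000, ac)
  set.seed(5); b <- simulate_alpha_dose(vol, "caf", 2000, ac)
  expect_identical(a$tally_MeV, b$tally_MeV)
  expect_error(simulate_alpha_dose(vol, "caf", 2000, fx_lu()), "no alpha lines")
  empty <- structure(list(labels = array(1L, c(4, 4, 4)),
                          grid = grid_spec(20, c(4, 4, 4), "center"),
                          density = 1.05, provenance = list()),
                     class = "label_volume")
  expect_error(simulate_alpha_dose(empty, "caf", 10, ac), "no source voxels")
})

test_that("a sub-voxel-range electron line concentrates the kernel in its center", {
  # synthetic scheme: single 1 keV line (range << 20 um)
  sch <- structure(list(nuclide = "test",
                        beta_branches = data.frame(endpoint_MeV = 1e-3,
                                                   yield = 1, daughter_Z = 1),
                        electron_lines = data.frame(energy_MeV = numeric(),
                                                    yield = numeric()),
                        alpha_lines = data.frame()), class = "decay_scheme")
  set.seed(3)
  k <- generate_beta_kernel(sch, shape = 11, primaries = 1e4, n_batches = 5,
                            symmetrize = FALSE)
  c0 <- (11 + 1) / 2
  # decays sampled at the voxel boundary may deposit in a face neighbor, but
  # essentially all energy stays in the source voxel
  expect_equal(which.max(k$values), (11^3 + 1) %/% 2)
  expect_gt(k$values[c0, c0, c0] / sum(k$values), 0.99)
  off <- abs(slice.index(k$values, 1) - c0) + abs(slice.index(k$values, 2) - c0) +
    abs(slice.index(k$values, 3) - c0)
  expect_true(all(k$values[off > 1] == 0))
})

test_that("Lu-177 kernel is centered, contained and octant-symmetric in expectation", {
  set.seed(21)
  k <- generate_beta_kernel(fx_lu(), shape = 121, primaries = 4e4,
                            n_batches = 10, symmetrize = TRUE)
  expect_equal(which.max(k$values), (prod(rep(121, 3)) + 1) %/% 2)
  # the 121^3 cube (1.2 mm half-width) misses part of the 1.8 mm endpoint
  # range, but straight-track containment must still be high
  expect_gt(k$contained_fraction, 0.97)
  expect_true(all(k$values >= 0))
  expect_error(generate_beta_kernel(fx_lu(), shape = 120, primaries = 1e4),
               "odd")
  expect_error(generate_beta_kernel(fx_lu(), shape = 121, primaries = 100),
               "1e4")
  # radial profile of the raw kernel agrees with its 48-fold symmetrization
  # within Monte Carlo noise (isotropy)
  set.seed(22)
  kr <- generate_beta_kernel(fx_lu(), shape = 61, primaries = 4e4,
                             n_batches = 10, symmetrize = FALSE)
  ks <- kr; ks$values <- voxdosim:::.symmetrize_cube(kr$values)
  x <- seq_len(61) - 31
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  bins <- cut(r, c(-0.5, 1.5, 3, 5, 8, 12))
  raw <- tapply(kr$values, bins, sum)
  sym <- tapply(ks$values, bins, sum)
  expect_lt(max(abs(raw - sym) / sym), 0.05)
})
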