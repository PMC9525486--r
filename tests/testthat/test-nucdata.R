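# decay schemes, beta spectrum sampling, stopping powers and range arithmetic

test_that("bundled decay schemes carry the expected physics", {
  ac <- fx_ac()
  expect_equal(round(ac$half_life_days, 0), 10)
  # four alphas per parent decay (chain), branch-weighted
  expect_gt(sum(ac$alpha_lines$yield), 3.9)
  expect_lt(sum(ac$alpha_lines$yield), 4.1)
  expect_true(all(ac$alpha_lines$energy_MeV > 4 & ac$alpha_lines$energy_MeV < 10))
  # chain structure: both Bi-213 branches represented
  expect_setequal(unique(ac$alpha_lines$nuclide),
                  c("Ac-225", "Fr-221", "At-217", "Bi-213", "Po-213"))

  lu <- fx_lu()
  expect_equal(round(lu$half_life_days, 1), 6.6)
  expect_true(all(lu$beta_branches$yield > 0 & lu$beta_branches$yield <= 1))
  expect_lte(sum(lu$beta_branches$yield), 1 + 1e-9)
  expect_true(all(lu$beta_branches$endpoint_MeV > 0))

  expect_error(load_decay_scheme("Tc-99m"), "unsupported")
})

test_that("beta sampling matches the numerical integral of the spectrum shape", {
  lu <- fx_lu()
  set.seed(101)
  E <- sample_beta_energies(lu, 1e5)
  expect_true(all(E > 0 & E <= max(lu$beta_branches$endpoint_MeV)))
  # oracle: mean energy by numeric integration of the same spectral shape,
  # mixed over branches by yield
  br <- lu$beta_branches
  mom <- vapply(seq_len(nrow(br)), function(i) {
    x <- seq(1e-6, br$endpoint_MeV[i], length.out = 4001)
    d <- beta_spectrum(x, br$endpoint_MeV[i], br$daughter_Z[i])
    c(mean = trapz(x, x * d) / trapz(x, d),
      m2 = trapz(x, x^2 * d) / trapz(x, d))
  }, c(mean = 0, m2 = 0))
  w <- br$yield / sum(br$yield)
  mu <- sum(w * mom["mean", ])
  sd1 <- sqrt(sum(w * mom["m2", ]) - mu^2)
  expect_lt(abs(mean(E) - mu), 3 * sd1 / sqrt(length(E)))

  # Kolmogorov distance between empirical and analytic mixture CDF < 0.01
  xg <- seq(1e-6, max(br$endpoint_MeV), length.out = 2001)
  cdf <- rowSums(vapply(seq_len(nrow(br)), function(i) {
    d <- beta_spectrum(xg, br$endpoint_MeV[i], br$daughter_Z[i])
    cs <- cumsum(c(0, (head(d, -1) + tail(d, -1)) / 2 * diff(xg)))
    w[i] * cs / cs[length(cs)]
  }, numeric(length(xg))))
  ks <- max(abs(stats::ecdf(E)(xg) - cdf))
  expect_lt(ks, 0.01)
})

test_that("beta sampling is deterministic under a fixed seed and bounded", {
  lu <- fx_lu()
  set.seed(7); a <- sample_beta_energies(lu, 1000)
  set.seed(7); b <- sample_beta_energies(lu, 1000)
  expect_identical(a, b)
  one <- data.frame(endpoint_MeV = 0.3, yield = 1, daughter_Z = 40)
  set.seed(1)
  expect_lt(sample_beta_energies(one, 1), 0.3)
  expect_error(sample_beta_energies(fx_ac(), 10), "no beta branches")
})

test_that("CSDA ranges behave physically and match a Simpson oracle", {
  spa <- fx_spt_a()
  ac <- fx_ac()
  r <- csda_range(spa, ac$alpha_lines$energy_MeV, density = 1.05)
  expect_true(all(r >= 40 & r <= 100))  # chain alphas stop within 40-100 um
  expect_identical(csda_range(spa, 0, 1.05), 0)
  Es <- c(0.5, 2, 5, 8)
  expect_true(all(diff(csda_range(spa, Es, 1.05)) > 0))
  expect_error(csda_range(spa, 50, 1.05), "domain")

  # independent oracle: Simpson integration of 1/S on a fine grid built from
  # the public table columns
  simpson_range <- function(tab, E) {
    n <- 4001
    x <- seq(tab$energy_MeV[1], E, length.out = n)
    S <- exp(approx(log(tab$energy_MeV), log(tab$stopping_MeV_cm2_g), log(x))$y)
    h <- diff(x)[1]
    w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
    (sum(w / S) * h / 3 + tab$energy_MeV[1] / S[1]) * 1e4
  }
  for (E in c(2, 5.8, 8.376))
    expect_lt(abs(csda_range(spa, E, 1) - simpson_range(spa, E)) /
                csda_range(spa, E, 1), 0.01)
  spe <- fx_spt_e()
  for (E in c(0.1, 0.4983))
    expect_lt(abs(csda_range(spe, E, 1) - simpson_range(spe, E)) /
                csda_range(spe, E, 1), 0.01)
})

test_that("electron range reproduces the maximal Lu-177 beta range scale", {
  # ~1.8 mm at unit density for the 497.8 keV endpoint
  r <- csda_range(fx_spt_e(), 0.4983, 1.0)
  expect_gt(r, 1600); expect_lt(r, 1900)
})

test_that("residual energy is the exact inverse of the range integral", {
  spa <- fx_spt_a()
  expect_identical(residual_energy(spa, 8, 0, 1.05), 8)
  R8 <- csda_range(spa, 8, 1.05)
  expect_lt(residual_energy(spa, 8, R8, 1.05), 1e-9)
  expect_error(residual_energy(spa, 8, -1, 1.05), "negative")
  # monotone non-increasing in path length
  s <- seq(0, R8, length.out = 50)
  expect_true(all(diff(residual_energy(spa, 8, s, 1.05)) <= 1e-12))
  # conservation identity: E - E_res(s) equals the energy deposited on [0, s]
  # integrated independently from the stopping power along the track
  for (E0 in c(2, 5.8, 8.376)) for (frac in c(0.25, 0.6, 0.9)) {
    s1 <- frac * csda_range(spa, E0, 1.05)
    u <- seq(0, s1, length.out = 2000)
    Eres <- residual_energy(spa, E0, u, 1.05)
    dep <- trapz(u, stopping_power(spa, pmax(Eres, 1e-9), 1.05) * 1e-4)
    expect_lt(abs(E0 - Eres[length(Eres)] - dep) / E0, 1e-3)
  }
  # and the table-consistent identity holds to near machine precision
  for (E0 in c(2, 5.8, 8.376)) {
    R0 <- csda_range(spa, E0, 1.05)
    mid <- residual_energy(spa, E0, 0.5 * R0, 1.05)
    rest <- csda_range(spa, mid, 1.05)
    expect_lt(abs(rest - 0.5 * R0) / R0, 1e-6)
  }
})
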