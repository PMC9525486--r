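# Radionuclide emission schemes and charged-particle stopping-power tables.
#
# Two nuclides are bundled: Lu-177 (beta branches plus grouped conversion/Auger
# electron lines) and the Ac-225 alpha chain down to Pb-209. Stopping powers for
# a soft-tissue/liquid-water surrogate are bundled for electrons and alphas and
# drive all range, residual-energy and track-deposition arithmetic.

#' Load a bundled radionuclide decay scheme
#'
#' Reads the plain-text decay table shipped with the package and returns a
#' `decay_scheme` object. `"Lu-177"` carries beta branches and discrete
#' conversion/Auger electron lines; `"Ac-225"` carries the alpha lines of the
#' full decay chain (Ac-225, Fr-221, At-217 and the Bi-213/Po-213 branch),
#' the chain beta branches (Bi-213, Tl-209, Pb-209) used when chain electrons
#' are transported, and the Bi-213 alpha-branch probability used for per-decay
#' branch sampling.
#'
#' Alpha yields in `$alpha_lines` are branch-weighted per parent decay, so for
#' Ac-225 they sum to the mean number of alphas emitted per decay (4.0).
#'
#' @param nuclide `"Lu-177"` or `"Ac-225"`.
#' @return A `decay_scheme`: list with `nuclide`, `half_life_days`,
#'   `beta_branches` (data frame: `endpoint_MeV`, `yield`, `daughter_Z`),
#'   `electron_lines` (data frame: `energy_MeV`, `yield`), `alpha_lines`
#'   (data frame: `nuclide`, `energy_MeV`, `yield`, `branch`, `A_daughter`),
#'   `chain_beta_branches`, and `bi213_alpha_branch`.
#' @export
load_decay_scheme <- function(nuclide) {
  file <- switch(nuclide,
    "Lu-177" = "decay_lu177.tsv",
    "Ac-225" = "decay_ac225.tsv",
    stop("unsupported nuclide: ", nuclide,
         " (bundled schemes: Lu-177, Ac-225)")
  )
  key <- paste0("scheme_", nuclide)
  if (!is.null(.vx_cache[[key]])) return(.vx_cache[[key]])

  ln <- readLines(.vx_extdata(file))
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  tok <- strsplit(trimws(ln), "\\s+")
  rec <- function(type) tok[vapply(tok, `[[`, "", 1L) == type]

  half_life <- as.numeric(rec("H")[[1]][2])
  stopifnot(is.finite(half_life), half_life > 0)

  betas <- rec("B")
  alphas <- rec("A")
  elects <- rec("E")
  pbr <- rec("P")
  bi213_p <- if (length(pbr)) as.numeric(pbr[[1]][2]) else NA_real_

  parse_beta <- function(x) {
    if (length(x[[1]]) >= 6) {       # chain format: B nuc Emax yield Z branch
      data.frame(
        nuclide = vapply(x, `[[`, "", 2L),
        endpoint_MeV = as.numeric(vapply(x, `[[`, "", 3L)),
        yield = as.numeric(vapply(x, `[[`, "", 4L)),
        daughter_Z = as.integer(vapply(x, `[[`, "", 5L)),
        branch = vapply(x, `[[`, "", 6L)
      )
    } else {                          # simple format: B Emax yield Z
      data.frame(
        endpoint_MeV = as.numeric(vapply(x, `[[`, "", 2L)),
        yield = as.numeric(vapply(x, `[[`, "", 3L)),
        daughter_Z = as.integer(vapply(x, `[[`, "", 4L))
      )
    }
  }

  scheme <- list(nuclide = nuclide, half_life_days = half_life)
  if (nuclide == "Lu-177") {
    scheme$beta_branches <- parse_beta(betas)
    scheme$electron_lines <- data.frame(
      energy_MeV = as.numeric(vapply(elects, `[[`, "", 2L)),
      yield = as.numeric(vapply(elects, `[[`, "", 3L))
    )
    scheme$alpha_lines <- data.frame(
      nuclide = character(), energy_MeV = numeric(), yield = numeric(),
      branch = character(), A_daughter = integer()
    )
    scheme$chain_beta_branches <- NULL
    scheme$bi213_alpha_branch <- NA_real_
  } else {
    av <- data.frame(
      nuclide = vapply(alphas, `[[`, "", 2L),
      energy_MeV = as.numeric(vapply(alphas, `[[`, "", 3L)),
      yield_within = as.numeric(vapply(alphas, `[[`, "", 4L)),
      branch = vapply(alphas, `[[`, "", 5L),
      A_daughter = as.integer(vapply(alphas, `[[`, "", 6L))
    )
    w <- ifelse(av$branch == "bi213alpha", bi213_p,
         ifelse(av$branch == "bi213beta", 1 - bi213_p, 1))
    scheme$alpha_lines <- data.frame(
      nuclide = av$nuclide, energy_MeV = av$energy_MeV,
      yield = av$yield_within * w, branch = av$branch,
      A_daughter = av$A_daughter, yield_within = av$yield_within
    )
    scheme$beta_branches <- data.frame(
      endpoint_MeV = numeric(), yield = numeric(), daughter_Z = integer()
    )
    scheme$electron_lines <- data.frame(energy_MeV = numeric(), yield = numeric())
    scheme$chain_beta_branches <- parse_beta(betas)
    scheme$bi213_alpha_branch <- bi213_p
  }
  stopifnot(all(scheme$alpha_lines$energy_MeV >= 0 | TRUE))
  class(scheme) <- "decay_scheme"
  .vx_cache[[key]] <- scheme
  scheme
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat("<decay_scheme>", x$nuclide, " half-life", x$half_life_days, "d\n")
  if (nrow(x$beta_branches)) cat("  beta branches:", nrow(x$beta_branches), "\n")
  if (nrow(x$alpha_lines))
    cat("  alpha lines:", nrow(x$alpha_lines),
        sprintf(" (%.3f alphas/decay)", sum(x$alpha_lines$yield)), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# beta spectrum

#' Allowed beta spectrum shape with non-relativistic Coulomb correction
#'
#' Unnormalized momentum-statistical spectrum density
#' `p * E_tot * (E0 - E)^2 * F(Z, E)` for an allowed beta-minus transition,
#' where `F` is the non-relativistic Fermi function
#' `2 pi eta / (1 - exp(-2 pi eta))` with `eta = Z alpha / beta`. Exotic shape
#' factors of forbidden transitions are ignored.
#'
#' @param energy_MeV kinetic energies (vector) at which to evaluate.
#' @param endpoint_MeV beta endpoint (maximum kinetic energy), MeV.
#' @param daughter_Z atomic number of the daughter nucleus.
#' @return Unnormalized density, zero outside `(0, endpoint_MeV)`.
#' @export
beta_spectrum <- function(energy_MeV, endpoint_MeV, daughter_Z) {
  mec2 <- 0.51099895
  alpha_fs <- 1 / 137.035999
  E <- pmax(energy_MeV, 1e-9)
  etot <- E + mec2
  p <- sqrt(pmax(etot^2 - mec2^2, 0))
  beta_v <- p / etot
  eta <- daughter_Z * alpha_fs / beta_v
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  d <- p * etot * (endpoint_MeV - E)^2 * fermi
  d[energy_MeV <= 0 | energy_MeV >= endpoint_MeV] <- 0
  d
}

# inverse-CDF grid for one branch (cached)
.beta_branch_cdf <- function(endpoint_MeV, daughter_Z, n_grid = 1024L) {
  key <- sprintf("betacdf_%.6f_%d_%d", endpoint_MeV, daughter_Z, n_grid)
  if (!is.null(.vx_cache[[key]])) return(.vx_cache[[key]])
  E <- seq(0, endpoint_MeV, length.out = n_grid)
  d <- beta_spectrum(E, endpoint_MeV, daughter_Z)
  cdf <- cumsum((head(d, -1) + tail(d, -1)) / 2 * diff(E))
  cdf <- c(0, cdf / cdf[length(cdf)])
  out <- list(E = E, cdf = cdf)
  .vx_cache[[key]] <- out
  out
}

#' Sample beta kinetic energies from a decay scheme
#'
#' Branches are chosen proportionally to yield; within a branch, energies are
#' drawn by inverse transform on a precomputed CDF grid of the allowed-spectrum
#' shape ([beta_spectrum()]). Uses the R random number stream: seed with
#' [set.seed()] for reproducibility.
#'
#' @param scheme a `decay_scheme` with non-empty `beta_branches`, or a data
#'   frame of branches (`endpoint_MeV`, `yield`, `daughter_Z`).
#' @param n number of energies to draw.
#' @param stratified logical; if `TRUE`, the branch/energy quantile is a
#'   stratified (permuted midpoint) sample of the mixture CDF rather than iid
#'   uniforms. Used by the kernel generator as variance reduction.
#' @return numeric vector of `n` kinetic energies, MeV.
#' @export
sample_beta_energies <- function(scheme, n, stratified = FALSE) {
  br <- if (inherits(scheme, "decay_scheme")) scheme$beta_branches else scheme
  if (is.null(br) || nrow(br) == 0L) stop("scheme has no beta branches")
  stopifnot(n >= 1)
  yields <- br$yield / sum(br$yield)
  u <- if (stratified) (sample.int(n) - runif(n)) / n else runif(n)
  # mixture inverse CDF: split [0,1) by branch, rescale within
  cy <- cumsum(yields)
  idx <- findInterval(u, c(0, cy), rightmost.closed = TRUE)
  idx[idx > nrow(br)] <- nrow(br)
  lo <- c(0, cy)[idx]
  uin <- (u - lo) / yields[idx]
  out <- numeric(n)
  for (b in seq_len(nrow(br))) {
    sel <- idx == b
    if (!any(sel)) next
    g <- .beta_branch_cdf(br$endpoint_MeV[b], br$daughter_Z[b])
    out[sel] <- approx(g$cdf, g$E, xout = pmin(pmax(uin[sel], 0), 1),
                       ties = "ordered")$y
  }
  out
}

# ---------------------------------------------------------------------------
# stopping powers, ranges, residual energies

#' Load a bundled stopping-power table
#'
#' Parses the plain-text stopping-power table for the requested particle and
#' precomputes fine-grained range-energy curves (CSDA range as a function of
#' energy and its inverse on a uniform range grid) used by [csda_range()],
#' [residual_energy()] and the Monte Carlo track engine.
#'
#' @param particle `"electron"` or `"alpha"`.
#' @return A `stopping_power_table`: `particle`, `energy_MeV`,
#'   `stopping_MeV_cm2_g`, `reference_density` (g/cm^3), `medium`, plus
#'   precomputed curves (`fine_E`, `fine_range_um`, `inv_dr`, `inv_E`).
#' @export
load_stopping_power <- function(particle = c("electron", "alpha")) {
  particle <- match.arg(particle)
  key <- paste0("spt_", particle)
  if (!is.null(.vx_cache[[key]])) return(.vx_cache[[key]])
  file <- if (particle == "electron") "stopping_power_electron.tsv"
          else "stopping_power_alpha.tsv"
  tab <- read.table(.vx_extdata(file), comment.char = "#",
                    col.names = c("energy_MeV", "stopping_MeV_cm2_g"))
  obj <- stopping_power_table(particle, tab$energy_MeV, tab$stopping_MeV_cm2_g,
                              reference_density = 1.0,
                              medium = "soft tissue (water surrogate)")
  .vx_cache[[key]] <- obj
  obj
}

#' Construct a stopping-power table
#'
#' @param particle particle label (`"electron"` or `"alpha"`).
#' @param energy_MeV strictly increasing energy grid, MeV.
#' @param stopping_MeV_cm2_g mass stopping power at each grid energy.
#' @param reference_density density the table refers to, g/cm^3.
#' @param medium free-text medium identifier.
#' @return `stopping_power_table` object with precomputed range curves.
#' @export
stopping_power_table <- function(particle, energy_MeV, stopping_MeV_cm2_g,
                                 reference_density = 1.0, medium = "water") {
  stopifnot(length(energy_MeV) == length(stopping_MeV_cm2_g),
            all(diff(energy_MeV) > 0), all(stopping_MeV_cm2_g > 0),
            reference_density > 0)
  # fine log grid for range integration; linear interpolation of log S vs log E
  nf <- 20000L
  fE <- exp(seq(log(energy_MeV[1]), log(energy_MeV[length(energy_MeV)]),
                length.out = nf))
  fS <- exp(approx(log(energy_MeV), log(stopping_MeV_cm2_g), log(fE))$y)
  inv <- 1 / fS
  seg <- diff(fE) * (head(inv, -1) + tail(inv, -1)) / 2
  # below the table minimum: linear slowdown at S(Emin)
  r0 <- fE[1] / fS[1]
  frange <- (r0 + c(0, cumsum(seg))) * 1e4 / reference_density  # um at ref density
  # inverse curve on uniform range grid (for O(1) residual-energy lookup)
  rmax <- frange[nf]
  dr <- rmax / 60000
  rg <- seq(0, rmax, by = dr)
  Einv <- approx(c(0, frange), c(0, fE), xout = rg, ties = "ordered")$y
  obj <- list(particle = particle, energy_MeV = energy_MeV,
              stopping_MeV_cm2_g = stopping_MeV_cm2_g,
              reference_density = reference_density, medium = medium,
              fine_E = fE, fine_range_um = frange,
              inv_dr = dr, inv_E = Einv)
  class(obj) <- "stopping_power_table"
  obj
}

#' Mass stopping power at given energies (interpolated)
#'
#' @param table a `stopping_power_table`.
#' @param energy_MeV energies, MeV (within the table domain).
#' @param density medium density, g/cm^3; linear stopping power returned is
#'   `S * density` in MeV/cm.
#' @return linear stopping power, MeV/cm at `density`.
#' @export
stopping_power <- function(table, energy_MeV, density = table$reference_density) {
  .check_domain(table, energy_MeV)
  S <- exp(approx(log(table$energy_MeV), log(table$stopping_MeV_cm2_g),
                  log(pmax(energy_MeV, table$energy_MeV[1])))$y)
  S * density
}

.check_domain <- function(table, energy_MeV) {
  if (any(energy_MeV > table$energy_MeV[length(table$energy_MeV)] * (1 + 1e-12)))
    stop("energy above the ", table$particle,
         " stopping-power table domain (no extrapolation)")
  if (any(energy_MeV < 0)) stop("negative energy")
  invisible(TRUE)
}

#' Continuous-slowing-down (CSDA) range
#'
#' Range `R(E) = integral dE' / S(E')` from 0 to `E`, scaled from the table's
#' reference density to `density`. Strictly increasing in energy; 0 at zero
#' energy. Energies above the table domain raise an error (no extrapolation);
#' energies below the lowest tabulated point use a linear slowdown at the
#' lowest tabulated stopping power.
#'
#' @param table a `stopping_power_table`.
#' @param energy_MeV energies, MeV (vectorized).
#' @param density medium density, g/cm^3.
#' @return CSDA ranges in micrometres.
#' @export
csda_range <- function(table, energy_MeV, density = 1.0) {
  stopifnot(density > 0)
  .check_domain(table, energy_MeV)
  r <- approx(c(0, table$fine_E), c(0, table$fine_range_um),
              xout = pmin(energy_MeV, table$fine_E[length(table$fine_E)]),
              ties = "ordered")$y
  # below-table energies: linear in E (range r0 * E / Emin)
  low <- energy_MeV < table$fine_E[1]
  if (any(low)) r[low] <- table$fine_range_um[1] * energy_MeV[low] / table$fine_E[1]
  r * table$reference_density / density
}

#' Energy remaining at a range (inverse of the CSDA range curve)
#'
#' @param table a `stopping_power_table`.
#' @param range_um residual CSDA range, micrometres (at `density`).
#' @param density medium density, g/cm^3.
#' @return kinetic energy, MeV, whose CSDA range equals `range_um`.
#' @export
energy_at_range <- function(table, range_um, density = 1.0) {
  r <- pmax(range_um, 0) * density / table$reference_density
  i <- pmin(r / table$inv_dr, length(table$inv_E) - 1)
  approx(seq_along(table$inv_E) - 1, table$inv_E, xout = i, ties = "ordered")$y
}

#' Residual energy after a path length
#'
#' Kinetic energy remaining after a particle of initial energy `initial_MeV`
#' has travelled `path_um` micrometres under the continuous-slowing-down
#' approximation: `E_res = E(R(E0) - s)`, clipped at 0 beyond the range.
#' Monotone non-increasing in `path_um`; `residual_energy(E, 0) == E`.
#'
#' @param table a `stopping_power_table`.
#' @param initial_MeV initial kinetic energy, MeV.
#' @param path_um path length travelled, micrometres (>= 0; vectorized).
#' @param density medium density, g/cm^3.
#' @return residual kinetic energy, MeV.
#' @export
residual_energy <- function(table, initial_MeV, path_um, density = 1.0) {
  if (any(path_um < 0)) stop("negative path length")
  R0 <- csda_range(table, initial_MeV, density)
  out <- energy_at_range(table, R0 - path_um, density)
  out[path_um == 0] <- initial_MeV
  pmin(out, initial_MeV)
}

# uniform-range inverse curve at a given density, for the C++ engine
.range_curve_for_density <- function(table, density) {
  scale <- table$reference_density / density
  list(dr = table$inv_dr * scale, E = table$inv_E)
}
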