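# Spherical-mass (SM) voxel model: sphere construction, tumor/CAF cluster label
# generation at controlled clustering levels, axis-raycast nearest-CAF distance
# fields and their mean (L_mean), and scale calibration to a target L_mean.

#' Grid specification for a voxel volume
#'
#' @param spacing isotropic voxel spacing, micrometres (default 20, the
#'   approximate diameter of a cell).
#' @param shape integer vector of voxel counts per axis (length 3, or 2 for
#'   section images).
#' @param origin_convention `"center"` (grid center coincides with the center
#'   voxel's center; requires odd shape for a symmetric sphere) or `"corner"`
#'   (grid center falls on a voxel corner). The package default for the
#'   spherical mass is `"center"`; see [build_spherical_mask()].
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(spacing = 20, shape, origin_convention = c("center", "corner")) {
  origin_convention <- match.arg(origin_convention)
  stopifnot(spacing > 0, all(shape >= 1))
  structure(list(spacing = spacing, shape = as.integer(shape),
                 origin_convention = origin_convention),
            class = "grid_spec")
}

# voxel-center world coordinates (um, sphere center at 0) along one axis
.axis_coords <- function(n, spacing, origin_convention) {
  if (origin_convention == "center") ((seq_len(n) - 1) - (n - 1) / 2) * spacing
  else (seq_len(n) - 0.5 - n / 2) * spacing
}

#' Build the spherical-mass voxel mask
#'
#' Marks voxels whose centers lie inside a sphere of the given diameter. The
#' inclusion criterion is convention-locked: with the default
#' center-at-voxel-center convention and a non-strict comparison
#' (`r^2 <= (d/2)^2`), a 3 mm sphere sampled at 20 um yields exactly
#' 1,767,063 voxels on a 151^3 grid. The alternative conventions are exposed
#' for sensitivity checks only.
#'
#' @param diameter_um sphere diameter, micrometres.
#' @param spacing voxel spacing, micrometres.
#' @param origin_convention see [grid_spec()].
#' @param inclusive logical; `TRUE` uses `<=` (the locked default).
#' @return list with `mask` (3D logical array), `grid` (a `grid_spec`) and
#'   `diameter_um`; class `sphere_mask`.
#' @export
build_spherical_mask <- function(diameter_um, spacing = 20,
                                 origin_convention = c("center", "corner"),
                                 inclusive = TRUE) {
  origin_convention <- match.arg(origin_convention)
  stopifnot(diameter_um > 0, spacing > 0)
  R <- diameter_um / 2
  n <- if (origin_convention == "center") 2L * floor(R / spacing) + 1L
       else 2L * ceiling(R / spacing)
  if (n < 1) stop("grid too small to contain the sphere")
  cc <- .axis_coords(n, spacing, origin_convention)
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  mask <- if (inclusive) r2 <= R^2 else r2 < R^2
  if (!any(mask)) stop("grid too small: no voxel center falls inside the sphere")
  structure(list(mask = mask,
                 grid = grid_spec(spacing, rep(n, 3L), origin_convention),
                 diameter_um = diameter_um),
            class = "sphere_mask")
}

#' Cluster specification for tumor/CAF label generation
#'
#' @param morphology one of `"interspersed-cubes"`, `"blob-field"`,
#'   `"few-large-blobs"`, `"shell"`. The four families span increasing
#'   clustering coarseness; `"shell"` (a CAF layer anchored to the sphere
#'   surface with tunable polar coverage) is the only family that reaches
#'   nearest-CAF mean distances near the sphere radius.
#' @param scale characteristic clustering scale, micrometres (> spacing). For
#'   cubes it is the lattice period, for blob fields the correlation length,
#'   for few-large-blobs the intended blob diameter, and for the shell family
#'   it maps monotonically to the polar coverage of the CAF layer (larger
#'   scale, smaller coverage, larger L_mean).
#' @param tumor_fraction fraction of inside voxels labelled tumor (default
#'   0.75; CAFs take the rest). Must be in (0, 1).
#' @param seed integer seed controlling the random degrees of freedom (lattice
#'   offset, noise field, blob seeds, shell orientation).
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(morphology = c("interspersed-cubes", "blob-field",
                                        "few-large-blobs", "shell"),
                         scale, tumor_fraction = 0.75, seed = 1L) {
  morphology <- match.arg(morphology)
  if (!(tumor_fraction > 0 && tumor_fraction < 1))
    stop("tumor_fraction must be in (0, 1): with no CAF (or no tumor) the ",
         "nearest-CAF distance is undefined everywhere")
  stopifnot(scale > 0)
  structure(list(morphology = morphology, scale = scale,
                 tumor_fraction = tumor_fraction, seed = as.integer(seed)),
            class = "cluster_spec")
}

# scalar ordering field per morphology; tumor voxels = lowest tumor_fraction
# quantile of the field among inside voxels (exact allocation by rank)
.morphology_field <- function(mask_obj, spec) {
  g <- mask_obj$grid
  n <- g$shape
  sp <- g$spacing
  cx <- .axis_coords(n[1], sp, g$origin_convention)
  arr3 <- function(v, axis) {
    if (axis == 1) array(v, n)
    else if (axis == 2) array(rep(v, each = n[1]), n)
    else array(rep(v, each = n[1] * n[2]), n)
  }
  switch(spec$morphology,
    "interspersed-cubes" = {
      P <- spec$scale
      if (P <= sp) stop("scale must exceed the voxel spacing")
      off <- runif(3, 0, P)
      cheb <- function(axis) {
        u <- ((cx + off[axis]) %% P) / P - 0.5
        arr3(abs(u), axis)
      }
      pmax(cheb(1), cheb(2), cheb(3))
    },
    "blob-field" = {
      sigma <- spec$scale / 2
      noise <- array(rnorm(prod(n)), n)
      gk <- function(axis) exp(-0.5 * (pmin(
        (seq_len(n[axis]) - 1), n[axis] - (seq_len(n[axis]) - 1)) * sp / sigma)^2)
      K <- arr3(gk(1), 1) * arr3(gk(2), 2) * arr3(gk(3), 3)
      sm <- Re(fft(fft(noise) * fft(K / sum(K)), inverse = TRUE)) / prod(n)
      sm
    },
    "few-large-blobs" = {
      R <- mask_obj$diameter_um / 2
      vol_t <- spec$tumor_fraction * 4 / 3 * pi * R^3
      k <- max(1L, min(64L, round(vol_t / (pi / 6 * spec$scale^3))))
      # random seed points inside the sphere
      pts <- matrix(numeric(0), 0, 3)
      while (nrow(pts) < k) {
        cand <- matrix(runif(3 * 2 * k, -R, R), ncol = 3)
        cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts <- pts[seq_len(k), , drop = FALSE]
      w <- runif(k, 0.85, 1.15)  # mild size irregularity
      f <- array(Inf, n)
      X <- arr3(cx, 1); Y <- arr3(cx, 2); Z <- arr3(cx, 3)
      for (j in seq_len(k))
        f <- pmin(f, w[j] * sqrt((X - pts[j, 1])^2 + (Y - pts[j, 2])^2 +
                                 (Z - pts[j, 3])^2))
      f
    },
    "shell" = {
      # eccentric shell: tumor = ball centered at radial offset t*R along a
      # random axis, CAF = complement. t = 0 gives a concentric peripheral
      # CAF shell (L_mean ~ 400 um at 3 mm); as t -> 1 the CAF collects into
      # a crescent on the far side and L_mean grows continuously toward the
      # sphere diameter scale.
      R <- mask_obj$diameter_um / 2
      t_off <- min(1.4, max(0, (spec$scale / mask_obj$diameter_um - 2 / 15) / 0.6))
      # fixed grid-diagonal offset axis: orientation is irrelevant to the
      # isotropic-emission dosimetry, and a deterministic axis keeps the
      # calibrated L_mean stable across label seeds
      u <- c(1, 1, 1) / sqrt(3) * t_off * R
      X <- arr3(cx, 1); Y <- arr3(cx, 2); Z <- arr3(cx, 3)
      sqrt((X - u[1])^2 + (Y - u[2])^2 + (Z - u[3])^2)
    }
  )
}

#' Generate tumor/CAF cluster labels inside a spherical mask
#'
#' Partitions the inside voxels into tumor (label 1) and CAF (label 2) by
#' thresholding a morphology-specific scalar field at the exact
#' `tumor_fraction` rank, so the global tumor fraction is honoured to within
#' one voxel regardless of clustering scale. Outside voxels keep label 0.
#' Reproducible: the same `cluster_spec` yields the same labels.
#'
#' @param mask_obj a `sphere_mask` from [build_spherical_mask()].
#' @param spec a `cluster_spec`.
#' @param density tissue mass density, g/cm^3 (default 1.05, liver-like).
#' @return a `label_volume`: list with `labels` (3D integer array, 0 = outside,
#'   1 = tumor, 2 = CAF), `grid`, `density`, `provenance`.
#' @export
generate_cluster_labels <- function(mask_obj, spec, density = 1.05) {
  stopifnot(inherits(mask_obj, "sphere_mask"), inherits(spec, "cluster_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  f <- .morphology_field(mask_obj, spec)
  inside <- which(mask_obj$mask)
  n_in <- length(inside)
  k_tumor <- round(spec$tumor_fraction * n_in)
  if (k_tumor < 1 || k_tumor >= n_in)
    stop("infeasible tumor_fraction for this mask (", n_in, " inside voxels)")
  fv <- f[inside] + runif(n_in) * 1e-9  # break ties reproducibly
  ord <- order(fv)
  labels <- array(0L, dim(mask_obj$mask))
  labels[inside] <- 2L
  labels[inside[ord[seq_len(k_tumor)]]] <- 1L
  structure(list(labels = labels, grid = mask_obj$grid, density = density,
                 provenance = list(morphology = spec$morphology,
                                   scale = spec$scale,
                                   tumor_fraction = spec$tumor_fraction,
                                   seed = spec$seed,
                                   diameter_um = mask_obj$diameter_um)),
            class = "label_volume")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Tumor fraction of a label volume
#'
#' Tumor voxels divided by inside (tumor + CAF) voxels.
#' @param labels a `label_volume` or a labels array.
#' @return fraction in (0, 1).
#' @export
tumor_fraction <- function(labels) {
  L <- if (inherits(labels, "label_volume")) labels$labels else labels
  sum(L == 1L) / sum(L != 0L)
}

# ---------------------------------------------------------------------------
# axis-raycast nearest-CAF distances

# steps to first CAF looking backwards along the 3rd dim; Inf when the ray
# meets an outside voxel or the array edge first
.scan_back_dim3 <- function(caf, outside) {
  d <- dim(caf)
  out <- array(Inf, d)
  if (d[3] < 2L) return(out)
  prev <- matrix(Inf, d[1], d[2])
  for (k in 2:d[3]) {
    cur <- prev + 1
    cur[caf[, , k - 1L]] <- 1
    cur[outside[, , k - 1L]] <- Inf
    out[, , k] <- cur
    prev <- cur
  }
  out
}

#' Axis-raycast distance from each tumor voxel to the nearest CAF
#'
#' For every tumor voxel, casts rays along the cartesian directions (6 in 3D,
#' 4 in 2D) and records the number of voxel steps to the first CAF voxel on
#' each ray; the distance L is the minimum over directions times the voxel
#' spacing. A ray that reaches an outside voxel (label 0) or the array edge
#' without meeting a CAF contributes no candidate; tumor voxels with no
#' candidate in any direction are flagged undefined (not zero). A tumor voxel
#' face-adjacent to a CAF has L = spacing (one step); distances are always
#' positive integer multiples of the spacing.
#'
#' @param labels a `label_volume`, or a 2D/3D array with labels
#'   {0 = outside/background, 1 = tumor, 2 = CAF}.
#' @param spacing voxel spacing in micrometres (taken from the `label_volume`
#'   grid when available).
#' @param combine `"min"` (default, the nearest-CAF distance) or `"mean"`
#'   (mean of the per-direction distances over the defined directions of each
#'   voxel). The mean variant is a diagnostic: it is insensitive to septum
#'   thickness and quantifies how strongly a reported clustering length
#'   depends on the distance convention.
#' @return an `lfield`: list with `distance_um` (array, NA outside tumor and
#'   at undefined tumor voxels), `undefined` (logical array, TRUE at tumor
#'   voxels with no hit), `directions` (4 or 6), `spacing`, `combine`.
#' @export
compute_nearest_caf_distances <- function(labels, spacing = NULL,
                                          combine = c("min", "mean")) {
  combine <- match.arg(combine)
  if (inherits(labels, "label_volume")) {
    if (is.null(spacing)) spacing <- labels$grid$spacing
    L <- labels$labels
  } else L <- labels
  if (is.null(spacing)) spacing <- 20
  two_d <- length(dim(L)) == 2L || is.matrix(L)
  if (two_d) L <- array(L, c(dim(L), 1L))
  caf <- L == 2L
  outside <- L == 0L
  tumor <- L == 1L
  if (!any(caf)) stop("no CAF voxel in the volume: L is undefined everywhere")
  axes <- if (two_d) 1:2 else 1:3
  if (combine == "min") {
    steps <- array(Inf, dim(L))
  } else {
    ssum <- array(0, dim(L))
    scnt <- array(0L, dim(L))
  }
  for (ax in axes) {
    perm <- switch(ax, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    inv <- order(perm)
    cafp <- aperm(caf, perm)
    outp <- aperm(outside, perm)
    fwd <- .scan_back_dim3(cafp, outp)
    rev_idx <- dim(cafp)[3]:1
    bwd <- .scan_back_dim3(cafp[, , rev_idx, drop = FALSE],
                           outp[, , rev_idx, drop = FALSE])[, , rev_idx, drop = FALSE]
    if (combine == "min") {
      steps <- pmin(steps, aperm(fwd, inv), aperm(bwd, inv))
    } else {
      for (d in list(aperm(fwd, inv), aperm(bwd, inv))) {
        fin <- is.finite(d)
        ssum[fin] <- ssum[fin] + d[fin]
        scnt[fin] <- scnt[fin] + 1L
      }
    }
  }
  if (combine == "mean") {
    steps <- ifelse(scnt > 0L, ssum / pmax(scnt, 1L), Inf)
  }
  dist <- steps * spacing
  dist[!tumor] <- NA_real_
  undefined <- tumor & !is.finite(steps)
  dist[undefined] <- NA_real_
  if (two_d) {
    dist <- dist[, , 1L]
    undefined <- undefined[, , 1L]
  }
  structure(list(distance_um = dist, undefined = undefined,
                 directions = if (two_d) 4L else 6L, spacing = spacing,
                 combine = combine),
            class = "lfield")
}

#' Mean nearest-CAF distance (L_mean)
#'
#' Arithmetic mean of the defined axis-raycast distances of an `lfield`
#' returned by [compute_nearest_caf_distances()]. Undefined tumor voxels are
#' excluded, not zero-filled.
#'
#' @param field an `lfield`.
#' @return L_mean in micrometres.
#' @export
l_mean <- function(field) {
  d <- field$distance_um[is.finite(field$distance_um)]
  if (!length(d)) stop("all tumor voxels have undefined nearest-CAF distance")
  mean(d)
}

#' Fraction of tumor voxels with undefined nearest-CAF distance
#' @param field an `lfield`.
#' @return fraction in \[0, 1\].
#' @export
undefined_fraction <- function(field) {
  n_def <- sum(is.finite(field$distance_um))
  n_undef <- sum(field$undefined)
  n_undef / (n_def + n_undef)
}

# ---------------------------------------------------------------------------
# calibration

#' Calibrate a morphology scale to a target L_mean
#'
#' Monotone bisection on the clustering scale so that the generated model's
#' L_mean matches `target_lmean` within a relative tolerance. L_mean is a
#' non-decreasing function of scale for every bundled morphology family.
#'
#' @param mask_obj a `sphere_mask`.
#' @param morphology morphology family (see [cluster_spec()]).
#' @param target_lmean target mean nearest-CAF distance, micrometres; must be
#'   at least the voxel spacing.
#' @param tolerance relative tolerance on the achieved L_mean (default 0.02).
#' @param seed seed passed to the generated `cluster_spec`.
#' @param tumor_fraction tumor fraction (default 0.75).
#' @param bracket optional length-2 numeric scale bracket, micrometres.
#' @param max_iter bisection iteration cap.
#' @return the calibrated `cluster_spec`, with attributes `achieved_lmean` and
#'   `undefined_fraction`.
#' @export
calibrate_scale_to_lmean <- function(mask_obj, morphology, target_lmean,
                                     tolerance = 0.02, seed = 1L,
                                     tumor_fraction = 0.75, bracket = NULL,
                                     max_iter = 40L) {
  sp <- mask_obj$grid$spacing
  if (target_lmean < sp)
    stop("target_lmean below the voxel spacing (", sp, " um) is unreachable: ",
         "distances are positive multiples of the spacing")
  if (is.null(bracket)) {
    d <- mask_obj$diameter_um
    bracket <- switch(morphology,
      # lower bound at 3 voxels: near-voxel periods alias against the grid
      # and produce spurious coherent domains
      "interspersed-cubes" = c(3 * sp, 2 * d),
      "blob-field" = c(1.55 * sp, d),
      "few-large-blobs" = c(3 * sp, 3 * d),
      "shell" = c(0.134 * d, 3 * d))
  }
  eval_scale <- function(s) {
    spec <- cluster_spec(morphology, s, tumor_fraction, seed)
    fld <- compute_nearest_caf_distances(generate_cluster_labels(mask_obj, spec))
    list(spec = spec, lmean = l_mean(fld), undef = undefined_fraction(fld))
  }
  lo <- eval_scale(bracket[1]); hi <- eval_scale(bracket[2])
  if (target_lmean > hi$lmean * (1 + tolerance))
    stop(sprintf(paste0("target L_mean %.0f um unreachable for morphology '%s' ",
                        "in this mask (max reachable ~ %.0f um)"),
                 target_lmean, morphology, hi$lmean))
  if (target_lmean < lo$lmean * (1 - tolerance))
    stop(sprintf(paste0("target L_mean %.0f um unreachable for morphology '%s' ",
                        "(min reachable ~ %.0f um)"),
                 target_lmean, morphology, lo$lmean))
  best <- if (abs(lo$lmean - target_lmean) < abs(hi$lmean - target_lmean)) lo else hi
  a <- bracket[1]; b <- bracket[2]
  for (i in seq_len(max_iter)) {
    if (abs(best$lmean - target_lmean) / target_lmean <= tolerance) break
    m <- sqrt(a * b)  # geometric midpoint: scale spans decades
    cur <- eval_scale(m)
    if (abs(cur$lmean - target_lmean) < abs(best$lmean - target_lmean)) best <- cur
    if (cur$lmean < target_lmean) a <- m else b <- m
    if (b / a < 1.0005) break
  }
  if (abs(best$lmean - target_lmean) / target_lmean > tolerance)
    stop(sprintf("calibration did not converge: best L_mean %.1f vs target %.1f",
                 best$lmean, target_lmean))
  out <- best$spec
  attr(out, "achieved_lmean") <- best$lmean
  attr(out, "undefined_fraction") <- best$undef
  out
}
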